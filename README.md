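# adipometh

An integrative pipeline for case/control studies of adipocyte DNA
methylation in severe obesity — for epigeneticists and statistical
geneticists who need the full analysis chain from beta-value matrices to
causal inference as tested, reusable R functions rather than a one-off
script stack.

The pipeline covers:

- **EWAS**: per-CpG regression of methylation (beta values, β ∈ [0,1]) on
  obesity status with biological covariates and control-probe principal
  components; fixed-effects inverse-variance meta-analysis across a
  discovery and a replication cohort (β̄ = Σwᵢβᵢ/Σwᵢ, wᵢ = 1/seᵢ², with
  Cochran's Q and I²); a three-part replication gate (discovery FDR < 0.01;
  replication FDR < 0.01 with consistent direction; combined P < 1×10⁻⁷).
- **Sentinels and DMRs**: single-linkage chaining of significant sites
  within 5 kb into loci, minimum-p sentinels, and DMR extension (≥5
  direction-consistent, Bonferroni-significant sites within ±5 kb).
- **Exact binomial sign tests** computed in log space, so tail
  probabilities far below double underflow (log₁₀ p ≈ −1100) remain exact.
- **Matched permutation enrichment**: 1,000 methylation-matched background
  sites per sentinel via a sliding tolerance ladder (mean ±0.025·r,
  sd ±0.0025·r), then feature, GWAS/chromatin-state and pathway enrichment
  with fold and empirical p-values.
- **Target genes**: exclusive three-tier assignment (genic overlap →
  chromatin-interaction target → shared TAD after hierarchy merge) and
  methylation–expression association with a per-participant random
  intercept fitted by profile REML (y = α + β·meth + γ'C + u + ε,
  u ~ N(0, σᵤ²)).
- **Mendelian randomisation**: cis-mQTL instrument scan (±500 kb,
  palindromic MAF > 0.42 removed), Bonferroni instrument gate, LD clumping
  (r² < 0.01), Wald ratio / IVW estimates, MR-Egger and heterogeneity
  sensitivity at r² < 0.8, Steiger directionality (Fisher-z comparison of
  instrument r² on exposure vs outcome), FDR-gated causal flags.
- **TF mediation**: TF–sentinel methylation correlation, TF→target
  associations with and without methylation adjustment, and CG positional
  profiles around binding motifs.

A synthetic cohort generator (`simulate_cohort()`) plants known
case/control shifts, mQTLs, SNP→CpG→phenotype chains, methylation→expression
links and TF mediation triples, records them in a truth table, and backs the
calibration and recovery tests of every stage.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script regenerates the same deterministic synthetic study (8,000 CG sites,
two cohorts × two depots × 48 samples, a 500-individual mQTL reference
panel) and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # study matrices + planted truth
Rscript analysis/02_ewas.R        # per-depot EWAS, meta-analysis, gate
Rscript analysis/03_sentinels.R   # loci, sentinels, DMRs, depot concordance
Rscript analysis/04_enrichment.R  # matched-permutation enrichment
Rscript analysis/05_targets.R     # TAD merge, target tiers, meth-expr model
Rscript analysis/06_mr.R          # two-sample MR with Steiger gating
Rscript analysis/07_tfmed.R       # TF mediation contrasts, motif CG profile
```

Output from a run of steps 02–06:

```
[subq] 111/112 discovery-significant sites direction-consistent in replication (sign test log10 P = -31.7)
[subq] 100 sites pass the full gate; 100/159 planted recovered, 0 false positives
[subq] 83 loci from 100 gated sites; 2 flagged as DMRs (>=5 consistent flanking sites)
subq sentinels in visc: 75/83 direction-consistent (67 also Bonferroni-significant), sign test P = 9.1e-15
     label observed expected      fold     fisher_p empirical_p direction
2 enhancer       43   16.322 2.6344811 2.263186e-09 0.000999001  enriched
29 sentinel-trait tests; 8 flagged causal (MR FDR<0.01, Steiger FDR<0.01, exposure->outcome)
forward chains flagged: 8/8; reverse chains rejected: 2/2; untestable sentinels: 1
mean causal estimate at flagged forward chains: 0.209 (planted 0.20)
```

Reading this: every site that passed the replication gate was a planted
effect (no false positives at these sizes); both planted clustered-effect
regions were flagged as DMRs in both depots; the planted 3-fold enhancer
enrichment is recovered as 2.63-fold with the smallest possible empirical p
(1/1001); all eight planted forward causal chains are flagged with the
causal estimate recovering the planted coefficient 0.2, while both
reverse-direction chains are rejected by the Steiger directionality gate.

## Layout

```
R/                 implementation: io, synthdata, ewas, sentinels,
                   enrichment, targets, mr, tfmed
analysis/          numbered workflow drivers (thin, narrative)
tests/testthat/    unit, property and acceptance suites
scripts/           acceptance.R
vignettes/         methods vignette: models, assumptions, design choices
```
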