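---
title: "Methods: an integrative adipocyte methylome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrative adipocyte methylome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`adipometh` re-implements, as a tested pipeline, the analysis chain used in
case/control studies of adipocyte DNA methylation in severe obesity: per-site
epigenome-wide association in two cohorts, inverse-variance meta-analysis and
replication gating, sentinel and DMR definition, matched-background
permutation enrichment, hierarchical target-gene assignment,
methylation-expression association with a participant random intercept,
two-sample Mendelian randomisation with directionality testing, and
transcription-factor mediation contrasts. Every stage is exercised against a
synthetic cohort generator that plants known effects and records them in a
machine-readable truth table, so calibration and parameter recovery are
testable end to end.

## The statistical models

### Per-site association and meta-analysis

Methylation is quantified as a beta value, the fraction methylated at a CG
site, in [0, 1]. `site_association()` fits, per site, the ordinary least
squares model

  beta = b0 + b1 * obesity + g' * covariates + e,

with obesity status the predictor, so `b1` is the case-minus-control
methylation difference in fraction units (rendered as %-methylation in
reports). Covariates are age, sex, ethnicity and the leading principal
components of control-probe intensities (`control_probe_pcs()`), which absorb
technical staining/extension/bisulphite-conversion variation; the smallest
number of components whose cumulative explained variance reaches 95% is used.
Missing betas are handled by listwise deletion per site; sites with fewer
than rank + 3 complete observations are skipped and flagged. Two cohorts are
combined by fixed-effects inverse-variance weighting (`ivw_meta()`), with
Cochran's Q and I-squared reported but not used as a gate — heterogeneity is
evaluated, not filtered on.

The replication gate (`replication_gate()`) follows the three-part rule:
discovery FDR < 0.01, replication FDR < 0.01 with consistent direction, and
combined fixed-effects P < 1e-7 (epigenome-wide significance). The
combined-P gate uses the fixed-effects IVW p-value; a random-effects variant
was considered unnecessary because the gate already demands per-cohort
replication. FDR control is Benjamini-Hochberg throughout (`bh_fdr()`), a
deliberate, parameter-free substitution for density-estimating q-value
methods; at the thresholds used the two rarely disagree.

### Quantile normalisation

`quantile_normalize()` replaces each sample's sorted values with the
cross-sample mean of order statistics (ties receive the mean of the reference
values their rank range spans; samples with missing values are mapped through
interpolated reference quantiles). On complete data this reproduces the
classic limma algorithm to 1e-10, which the test suite checks explicitly as
a dual-route comparison.

### Sentinels, DMRs and sign tests

Significant sites at most 5,000 bp apart on one chromosome are chained into a
locus (`clump_loci()`). Chaining is transitive single linkage — the phrase
"within 5 kb of each other" reads pairwise, and the transitive closure is its
deterministic completion — so a chain's ends may be farther than 5 kb apart.
A windowed alternative (claim everything within 5 kb of the best remaining
site) is available behind `method = "window"`. The sentinel is the
minimum-p member, ties broken by lower genomic position for determinism.

`extend_dmr()` flags a differentially methylated region when at least five
sites within 5 kb of the sentinel share its direction of effect at a
Bonferroni-adjusted p < 0.05. The Bonferroni denominator is not fully
specified in the source description; we default to the number of array sites
inside the tested window and expose it (`bonf_n`) because the count is
monotone non-increasing in the denominator, making the default the most
permissive defensible choice and any study-wide denominator strictly
stricter.

Direction-consistency tests use `exact_binomial()`, computed entirely in log
space by log-sum-exp over binomial log-probabilities, so tails far below
double-precision underflow (e.g. log10 p near -1100) are exact. The
two-sided test doubles the smaller tail (including the observed count) and
caps at 1; at p0 = 0.5 this equals the minimum-likelihood two-sided test by
symmetry.

### Matched permutation backgrounds

Array content is biased towards CpG islands and annotated genes, so
enrichment is judged against methylation-matched backgrounds rather than the
genome. For each sentinel, `build_permutation_set()` walks a tolerance
ladder: rung r accepts pool sites within 0.025·r of the sentinel's mean and
0.0025·r of its standard deviation, at least 5 kb away; the first rung with
strictly more than 1,000 candidates is accepted, and exactly 1,000 are
sampled without replacement. Sampling uses a per-sentinel stream seeded by
XOR of the global seed and the sentinel index, so sets regenerate exactly and
are independent across sentinels. Matched sites may recur across different
sentinels' sets; uniqueness is required only within a set. Background
replicate j is formed by the j-th matched site of every sentinel, keeping
replicates the same size as the sentinel list so the Fisher and empirical
tests are comparable. The empirical p is (1 + #{replicates at least as
extreme}) / (N + 1) and can never be smaller than 1/(N+1).

For GWAS overlap the question is interval-level: a sentinel counts if the
chromatin-state interval containing it also contains a genome-wide
significant SNP. A label-level variant (same state label anywhere) is
available behind `label_level = TRUE`; interval-level is the default because
state labels recur genome-wide and label-level matching dilutes the signal
to near-uniformity.

### Target genes and the random-intercept model

Candidate effector genes are assigned by three exclusive tiers
(`assign_targets()`): (1) genic — the sentinel overlaps an exon, UTR or the
promoter window (TSS ± 5 kb); (2) functional — only if tier 1 is empty, the
sentinel sits in a distal interval connected to a gene by a chromatin
interaction map; (3) TAD — only if both earlier tiers are empty, all genes
whose TSS shares a topologically associated domain with the sentinel. TADs
are first cleaned of hierarchy by `merge_tads()`, which removes every
interval strictly contained in another, keeping the largest domains;
partial overlaps are retained and the operation is idempotent.

Methylation-expression association (`meth_expr_assoc()`) uses combined
subcutaneous and visceral samples; because the two depots of one individual
are correlated, the model carries a per-participant random intercept:

  logCPM = a + b * beta + g' * covariates + u_participant + e,
  u ~ N(0, sigma_u^2).

The fitter (`fit_random_intercept()`) profiles restricted maximum likelihood
over the single variance ratio lambda = sigma_u^2/sigma_e^2 with closed-form
generalised least squares at each lambda, using the per-group Woodbury
identity, plus an explicit evaluation at the OLS boundary lambda = 0. With
exactly one random effect this avoids any general mixed-model machinery while
matching `lme4::lmer` REML fits to four decimals on shared fixtures (a
dual-route check in the test suite); `reml_criterion()` exposes the profiled
criterion so the optimum can be audited against a grid. With singleton
groups the model collapses to OLS identically — the true degenerate limit —
and on paired data generated without a participant effect the estimated
intercept variance is small but not exactly zero, as for any REML estimator
at a boundary. Wald inference uses a t reference with n - p degrees of
freedom. logCPM is log2(count / effective library size × 1e6 + 0.5) with
median-of-ratios size factors; precision weighting of the voom type is out
of scope and the DE fit used for target enrichment (`de_fit_naive()`) is a
deliberately naive log-scale OLS stand-in for a count model, used only as
plumbing for `de_enrichment()`'s exact binomial.

### Mendelian randomisation

Instruments are cis-SNPs within 500 kb of a sentinel, tested by OLS of
methylation on effect-allele dosage in a large reference panel
(`mqtl_scan()`); strand-ambiguous palindromic SNPs (A/T, C/G) with MAF >
0.42 are removed before testing. Instrument selection demands p < 0.05
Bonferroni-corrected for the number of in-window SNPs tested for that
sentinel (a per-sentinel denominator, following the phrasing "corrected for
the number of SNPs"), then greedy LD clumping at dosage r² < 0.01
(`ld_clump()`; a bound of 1 or more is a no-op). Outcome rows are
harmonised by allele matching with strand-complement fallback
(`harmonise_outcome()`); flipping twice is the identity.

Causal estimates use the most powerful applicable method: the Wald ratio
(beta_out/beta_exp, first-order SE) for a single instrument, and
inverse-variance-weighted regression through the origin for several;
the IVW estimate equals the precision-weighted mean of per-SNP Wald ratios,
an identity the tests verify to 1e-10. The correlated-instrument sensitivity
re-run clumps at r² < 0.8 and adds multiplicative random-effects IVW (SE
inflated by sqrt(Q/df), floored at 1) and MR-Egger, whose intercept tests
directional pleiotropy, wherever at least three instruments survive.

Directionality uses the Steiger test: instrument r² on the exposure side
(t²/(t² + df) from the mQTL regression) versus the outcome side (the same
identity from GWAS beta, SE and n), compared via Fisher z-transformed
correlations for independent samples. A sentinel-trait pair is flagged
causal only if the MR q-value and the Steiger q-value both clear FDR < 0.01
with exposure-to-outcome direction; the two BH families are kept separate
(a joint family is one flag away) because the tests answer different
questions and pooling them couples their thresholds.

### TF mediation

`mediation_contrast()` fits the TF-target association twice on the identical
sample subset — without and with adjustment for sentinel methylation, both
with the participant random intercept — and reports the coefficient change
delta and delta/beta_unadjusted (flagged undefined when the unadjusted
coefficient is below 1e-6). No hypothesis test is attached to delta: the
source analysis visualises adjusted against unadjusted coefficients without
a significance rule, and we follow that, leaving formal indirect-effect
inference (Sobel, bootstrap) out of scope. `motif_cg_profile()` counts CG
positions by offset from motif centres, mirroring minus-strand occurrences,
and conserves the total overlap count.

## The synthetic cohort generator

`simulate_cohort()` emulates the study geometry: two cohorts (discovery,
replication), each with 24 case and 24 control participants by default, each
participant contributing one subcutaneous and one visceral sample (~96
samples per cohort), expression for the replication cohort only, and a
separate 500-individual reference panel for mQTL discovery. Defaults encode
the emulated conditions:

- Planted case/control shifts: |shift| ~ Uniform(0.01, 0.18) with 75%
  negative, matching the reported median (≈6%), range and hypomethylation
  bias; 70% of effects shared across depots, the rest depot-specific.
- Baseline betas from a bimodal logit-latent mixture typical of array data;
  noise is drawn on the logit-latent scale so its beta-scale spread (~0.05
  mid-range by default) tapers towards the boundaries, and values are
  clamped to [0, 1] with a warning if more than 1% of draws clamp. Per-site
  variance is not reported in the source; the 0.03-0.07 default range is an
  assumption from typical array data.
- Two clustered-effect regions (runs of neighbouring sites sharing one
  negative shift, placed in CGI-like dense stretches) so DMR extension has
  true positives; cluster count and all other knobs are configurable.
- cis-mQTLs at 0.05 beta-units per allele; SNPs in blocks of four with ~0.9
  within-block correlation (block-wise LD only — realistic decay patterns
  are a non-goal).
- Causal chains SNP -> CpG -> phenotype with methylation-phenotype
  coefficient 0.2, read out by a GWAS of 500,000. Reverse chains give the
  SNP a strong direct phenotype effect (0.5) and a weak induced methylation
  response (0.015 per allele): detectable as an instrument at the reference
  panel size, yet leaving the instrument's outcome r² above its exposure
  r², which is exactly the configuration the Steiger test must reject.
- Expression counts are negative-binomial (size 10) with log-mean linear in
  planted methylation and TF effects (path coefficients defined on the log2
  scale the models fit), a participant random intercept (sd 0.5) and
  log-normal library-size factors.

What the generator does not emulate — probe chemistry, realistic LD decay,
cell-composition heterogeneity, count overdispersion structure beyond a
single NB size — bounds what passing tests show: they demonstrate that the
estimators recover what was planted under the stated noise model, not that
the pipeline is robust to every artefact of real arrays.

## Numerical choices and degenerate inputs

- All genomic intervals use one internal convention, 0-based half-open; BED
  is consumed natively and 1-based site positions are converted on read. CG
  sites are width-1 ranges at the cytosine. Strand is ignored for overlaps
  (array methylation is strand-collapsed); gene strand places promoter
  windows only.
- Readers reject rather than repair: duplicated ids, out-of-range values and
  malformed lines are hard errors naming the offending file, line or cell.
  Matrix writers emit 17 significant digits so text round-trips are
  bit-exact.
- Sites with more than 10% missing betas in a cohort are excluded by default
  (the source is silent on missingness; the threshold is conservative and
  configurable); remaining missingness is handled by listwise deletion.
- Collinear covariates raise an error naming the columns (QR rank check).
- `exact_binomial()` caps two-sided values at 1; k = n/2 at p0 = 0.5 returns
  exactly 1.
- Monomorphic SNPs have undefined LD and are treated as independent during
  clumping, but flagged.
- The mediation contrast skips the adjusted fit when methylation is nearly
  collinear with TF expression (r² > 0.99) instead of reporting an unstable
  coefficient.

## Problem sizes

The bundled analysis workflow (`analysis/01_simulate.R` ...
`07_tfmed.R`) runs an 8,000-site, 800-gene, 200-SNP study; the test suite
uses 500-8,000 sites per case with up to 100 repeated seeds for calibration
checks and a 500-individual reference panel for MR power. These sizes were
chosen so each property is measured with comfortable statistical resolution
while a full run stays in the minutes range on a single core; all scale
linearly with the configured dimensions.

## Known limitations

- The per-site regression is OLS on beta values; beta-binomial or
  variance-stabilised alternatives are not implemented.
- The DE stand-in is a log-scale OLS, not a negative-binomial count model;
  its q-values feed only the target-enrichment binomial.
- One mixed-model fitter is provided (profile REML); the cross-package
  sensitivity comparison of alternative mixed-model implementations in the
  source analysis is not reproduced, though an OLS-with-cluster-flag
  fallback records non-convergence.
- Colocalisation, weighted-median/mode MR estimators and external reference
  panels are out of scope.
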