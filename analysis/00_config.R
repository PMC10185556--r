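# Shared study configuration for the analysis workflow. Every driver sources
# this file and regenerates the same synthetic study deterministically, so no
# intermediate binary objects are needed.

library(adipometh)

STUDY_SEED <- 20240901L

study_config <- function() {
  sim_config(
    n_sites = 8000,          # desk-scale stand-in for a 401k-site array
    n_genes = 800,
    n_snps = 200,
    n_cases = 24, n_controls = 24,   # per cohort; each participant gives both depots
    frac_diff = 0.02,
    effect_range = c(0.01, 0.18), frac_negative = 0.75,
    depot_shared_frac = 0.7,
    n_mqtl = 30, mqtl_shift = 0.08,
    n_chains = 8, chain_effect = 0.2, n_reverse_chains = 2,
    n_ref = 500, n_gwas = 5e5,
    n_target_links = 25, target_slope = -2,
    n_mediation = 6,
    enhancer_fold = 3,
    tad_nesting = 1,
    seed = STUDY_SEED)
}

get_study <- function() {
  cfg <- study_config()
  sim <- suppressWarnings(simulate_cohort(cfg))
  list(cfg = cfg, sim = sim, ann = simulate_annotations(cfg, sim))
}

# covariates used in every association model: age, sex, ethnicity plus the
# control-probe PCs explaining >= 95% of technical variance
ewas_covars <- function(sim, key) {
  sh <- sim$meth[[key]]$sample_sheet
  pcs <- control_probe_pcs(sim$controls[[key]], 0.95)
  cbind(age = sh$age, sex = sh$sex, ethnicity = sh$ethnicity, pcs)
}

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# bulky per-site/per-sample dumps go here; summary tables go under results/
scratch_dir <- function(...) {
  d <- file.path("scratch", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
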