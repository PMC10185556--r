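# Synthetic two-cohort, two-depot methylome study with planted truth.
#
# Study geometry mirrors a paired-depot case/control design: each synthetic
# participant contributes one subcutaneous and one visceral adipocyte sample;
# two independent cohorts (discovery/replication) are drawn from the same
# effect structure; expression is generated for the replication cohort only.
# Beta values are built as clamp(baseline + group effect + mQTL dosage effect
# + technical batch component + noise): baselines come from a bimodal
# logit-latent mixture typical of array data, planted case/control effects
# are additive mean shifts on the beta scale.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: ~48 samples per depot per
#' cohort (24 case + 24 control participants, each contributing both depots),
#' differential sites with |shift| ~ Uniform(0.01, 0.18) and 75% of shifts
#' negative (hypomethylation bias), cis-mQTLs at 0.05 beta-units per allele,
#' and SNP-methylation-phenotype causal chains read out by a large GWAS.
#'
#' @param n_sites number of CG sites.
#' @param n_genes number of genes.
#' @param n_snps number of SNPs (includes planted mQTL SNPs).
#' @param n_cases,n_controls participants per group per cohort.
#' @param frac_diff fraction of sites with a planted case/control shift.
#' @param effect_range range of |shift| (beta-scale fraction units).
#' @param frac_negative fraction of planted shifts that are negative.
#' @param depot_shared_frac fraction of planted effects present in both
#'   depots; the rest are depot-specific.
#' @param noise_sd_range per-site residual sd range (uniform draw).
#' @param batch_sd scale of the technical component shared with control
#'   probes.
#' @param n_mqtl planted cis-mQTLs; `mqtl_shift` per-allele beta shift.
#' @param mqtl_shift per-allele methylation shift of planted mQTLs.
#' @param maf_range minor allele frequency range of simulated SNPs.
#' @param n_chains planted SNP->CpG->phenotype causal chains (drawn from the
#'   planted mQTLs); `chain_effect` is the CpG->phenotype coefficient.
#' @param chain_effect methylation-to-phenotype path coefficient.
#' @param n_reverse_chains chains where the SNP acts on the phenotype first
#'   and methylation responds (to exercise directionality testing).
#' @param reverse_snp_cpg induced SNP-to-methylation effect of reverse chains
#'   (beta units per allele; weak but instrument-detectable at `n_ref`).
#' @param snp_phen_direct direct SNP-to-phenotype effect of reverse chains.
#' @param n_ref sample size of the mQTL reference panel (emulating a large
#'   whole-adipose-tissue methylation + genotype cohort).
#' @param n_gwas GWAS sample size used for outcome summary statistics.
#' @param n_target_links planted methylation-to-expression links;
#'   `target_slope` log-expression units per beta unit.
#' @param target_slope methylation-to-expression slope.
#' @param n_mediation planted TF -> sentinel methylation -> target triples.
#' @param mediation_paths named vector: tf_meth (beta units per log-expr
#'   unit), meth_target (log-expr per beta unit), tf_target_direct.
#' @param participant_sd expression random-intercept sd (log scale).
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param n_chrom chromosomes in the synthetic genome.
#' @param n_dmr_clusters clustered-effect regions (runs of neighbouring sites
#'   sharing one planted shift) that downstream DMR extension should find.
#' @param enhancer_base_rate background rate of the planted "enhancer" track.
#' @param enhancer_fold planted enrichment fold of differential sites in the
#'   enhancer track.
#' @param interaction_frac fraction of planted target links also wired into
#'   the distal-interaction map.
#' @param tad_nesting nested sub-domains per TAD (exercises hierarchy merge).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 20000, n_genes = 1500, n_snps = 300,
                       n_cases = 24, n_controls = 24,
                       frac_diff = 0.02, effect_range = c(0.01, 0.18),
                       frac_negative = 0.75, depot_shared_frac = 0.7,
                       noise_sd_range = c(0.03, 0.07), batch_sd = 0.01,
                       n_mqtl = 40, mqtl_shift = 0.05, maf_range = c(0.1, 0.45),
                       n_chains = 10, chain_effect = 0.2, n_reverse_chains = 0,
                       reverse_snp_cpg = 0.015, snp_phen_direct = 0.5,
                       n_ref = 500, n_gwas = 500000,
                       n_target_links = 30, target_slope = -2,
                       n_mediation = 8,
                       mediation_paths = c(tf_meth = 0.05, meth_target = -2,
                                           tf_target_direct = 0.3),
                       participant_sd = 0.5, nb_size = 10,
                       n_chrom = 4, n_dmr_clusters = 2,
                       enhancer_base_rate = 0.08, enhancer_fold = 1,
                       interaction_frac = 0.6, tad_nesting = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  fracs <- c(frac_diff, frac_negative, depot_shared_frac, interaction_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]")
  if (enhancer_fold * enhancer_base_rate > 1)
    stop(sprintf("requested enhancer fold unattainable: maximum achievable fold is %.2f",
                 1 / enhancer_base_rate))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# deterministic site/gene/snp placement along a synthetic genome; inter-site
# gaps are a mixture of sparse open-sea spacing and dense CGI-like runs
.sim_genome <- function(cfg) {
  per_chrom <- ceiling(cfg$n_sites / cfg$n_chrom)
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), each = per_chrom)[seq_len(cfg$n_sites)]
  dense <- runif(cfg$n_sites) < 0.25
  gaps <- ifelse(dense, 50L + as.integer(rexp(cfg$n_sites, 1 / 400)),
                 100L + as.integer(rexp(cfg$n_sites, 1 / 2200)))
  pos <- as.integer(unlist(lapply(split(gaps, chrom), cumsum), use.names = FALSE)) + 10000L
  data.frame(site_id = sprintf("cg%06d", seq_len(cfg$n_sites)),
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate the full two-cohort study
#'
#' @param cfg a [sim_config()].
#' @return list with elements `meth` (named list of `meth_matrix`, one per
#'   cohort x depot: disc_subq, disc_visc, repl_subq, repl_visc), `expr`
#'   (`expr_matrix` over the replication cohort, both depots), `geno`
#'   (`geno_matrix` over all participants), `ref` (mQTL reference panel:
#'   `meth` and `geno` over `n_ref` independent individuals, for instrument
#'   discovery), and `truth` (list of tables: sites, mqtl, chains, targets,
#'   mediation).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sites <- .sim_genome(cfg)
  n_sites <- cfg$n_sites

  # baseline betas: bimodal logit-latent mixture, planted sites kept mid-range
  comp <- sample(1:3, n_sites, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  latent <- c(-2.5, 2.5, 0)[comp] + rnorm(n_sites, 0, c(0.8, 0.8, 1)[comp])
  base <- plogis(latent)
  noise_sd <- runif(n_sites, cfg$noise_sd_range[1], cfg$noise_sd_range[2])

  # planted case/control effects
  n_diff <- round(cfg$frac_diff * n_sites)
  diff_idx <- sample(n_sites, n_diff)
  base[diff_idx] <- runif(n_diff, 0.25, 0.75)   # headroom for additive shifts
  shift <- runif(n_diff, cfg$effect_range[1], cfg$effect_range[2]) *
    ifelse(runif(n_diff) < cfg$frac_negative, -1, 1)
  shared <- runif(n_diff) < cfg$depot_shared_frac
  specific_depot <- ifelse(shared, NA, sample(c("subq", "visc"), n_diff, replace = TRUE))
  eff_subq <- numeric(n_sites); eff_visc <- numeric(n_sites)
  eff_subq[diff_idx] <- ifelse(shared | specific_depot == "subq", shift, 0)
  eff_visc[diff_idx] <- ifelse(shared | specific_depot == "visc", shift, 0)

  # clustered shifts: runs of neighbouring sites sharing one effect, giving
  # extended differentially methylated regions around their sentinels
  if (cfg$n_dmr_clusters > 0) {
    for (k in seq_len(cfg$n_dmr_clusters)) {
      # favour CGI-like dense runs: try candidate centres, keep the densest
      cand <- setdiff(seq_len(n_sites), diff_idx)
      trial <- cand[sample.int(length(cand), min(50, length(cand)))]
      counts <- vapply(trial, function(ct)
        sum(sites$chrom == sites$chrom[ct] &
              abs(sites$pos - sites$pos[ct]) <= 4000), 0L)
      centre <- trial[which.max(counts)]
      memb <- which(sites$chrom == sites$chrom[centre] &
                      abs(sites$pos - sites$pos[centre]) <= 4000)
      memb <- setdiff(memb, diff_idx)
      if (length(memb) < 3) next
      csh <- -runif(1, 0.06, 0.12)
      base[memb] <- runif(length(memb), 0.3, 0.7)
      eff_subq[memb] <- csh; eff_visc[memb] <- csh
      diff_idx <- c(diff_idx, memb)
      shift <- c(shift, rep(csh, length(memb)))
      shared <- c(shared, rep(TRUE, length(memb)))
      specific_depot <- c(specific_depot, rep(NA, length(memb)))
    }
    n_diff <- length(diff_idx)
  }

  # participants & genotypes (block-correlated SNPs)
  n_per <- cfg$n_cases + cfg$n_controls
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(2 * n_per)),
    cohort = rep(c("discovery", "replication"), each = n_per),
    group = rep(rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls)), 2),
    age = round(runif(2 * n_per, 25, 65)),
    sex = sample(c(0L, 1L), 2 * n_per, replace = TRUE),
    ethnicity = sample(c(0L, 1L, 2L), 2 * n_per, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)),
    stringsAsFactors = FALSE)
  n_all <- nrow(participants)

  maf <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  block <- (seq_len(cfg$n_snps) - 1L) %/% 4L
  dos <- matrix(0L, cfg$n_snps, n_all)
  for (b in unique(block)) {
    idx <- which(block == b)
    h1 <- rbinom(n_all, 1, maf[idx[1]]); h2 <- rbinom(n_all, 1, maf[idx[1]])
    for (k in idx) {
      flip <- 0.03
      d1 <- ifelse(runif(n_all) < flip, rbinom(n_all, 1, maf[k]), h1)
      d2 <- ifelse(runif(n_all) < flip, rbinom(n_all, 1, maf[k]), h2)
      dos[k, ] <- d1 + d2
    }
  }
  rownames(dos) <- sprintf("rs%05d", seq_len(cfg$n_snps))
  colnames(dos) <- participants$participant_id
  alle <- t(replicate(cfg$n_snps, sample(c("A", "C", "G", "T"), 2)))

  # planted mQTLs: SNP placed in cis of its site, non-palindromic alleles
  mqtl_site_idx <- diff_idx[sample.int(n_diff, min(cfg$n_mqtl, n_diff))]
  extra <- cfg$n_mqtl - length(mqtl_site_idx)
  if (extra > 0) {
    bgpool <- setdiff(seq_len(n_sites), diff_idx)
    mqtl_site_idx <- c(mqtl_site_idx, bgpool[sample.int(length(bgpool), extra)])
  }
  mqtl_snp_idx <- sample(cfg$n_snps, cfg$n_mqtl)
  pal <- c(A = "T", T = "A", C = "G", G = "C")
  for (j in seq_len(cfg$n_mqtl)) {
    si <- mqtl_site_idx[j]; sn <- mqtl_snp_idx[j]
    a1 <- sample(c("A", "C", "G", "T"), 1)
    a2 <- sample(setdiff(c("A", "C", "G", "T"), c(a1, pal[[a1]])), 1)
    alle[sn, ] <- c(a1, a2)
  }
  snp_chrom <- sample(sites$chrom, cfg$n_snps, replace = TRUE)
  snp_pos <- as.integer(runif(cfg$n_snps, 1e4, max(sites$pos)))
  snp_chrom[mqtl_snp_idx] <- sites$chrom[mqtl_site_idx]
  snp_pos[mqtl_snp_idx] <- pmax(1L, sites$pos[mqtl_site_idx] +
                                  as.integer(runif(cfg$n_mqtl, -2e5, 2e5)))
  mqtl_beta <- rep(cfg$mqtl_shift, cfg$n_mqtl)
  site_mqtl_beta <- numeric(n_sites)
  site_mqtl_beta[mqtl_site_idx] <- mqtl_beta
  site_mqtl_snp <- rep(NA_character_, n_sites)
  site_mqtl_snp[mqtl_site_idx] <- rownames(dos)[mqtl_snp_idx]

  # causal chains: forward (SNP->CpG->phenotype) and reverse
  n_chain <- min(cfg$n_chains + cfg$n_reverse_chains, cfg$n_mqtl)
  chain_pick <- sample(cfg$n_mqtl, n_chain)
  chain_dir <- rep(c("forward", "reverse"),
                   c(min(cfg$n_chains, n_chain), max(0, n_chain - cfg$n_chains)))
  chains <- data.frame(
    snp_id = rownames(dos)[mqtl_snp_idx[chain_pick]],
    site_id = sites$site_id[mqtl_site_idx[chain_pick]],
    snp_cpg_beta = mqtl_beta[chain_pick],
    cpg_phen_beta = rep(cfg$chain_effect, n_chain),
    direction = chain_dir,
    snp_phen_direct = ifelse(chain_dir == "reverse", cfg$snp_phen_direct, 0),
    maf = maf[mqtl_snp_idx[chain_pick]],
    stringsAsFactors = FALSE)
  # reverse chains: methylation responds weakly; SNP hits phenotype directly
  rev_rows <- chains$direction == "reverse"
  if (any(rev_rows)) {
    ridx <- match(chains$site_id[rev_rows], sites$site_id)
    site_mqtl_beta[ridx] <- cfg$reverse_snp_cpg
    chains$snp_cpg_beta[rev_rows] <- cfg$reverse_snp_cpg
  }

  # technical batch component shared with control probes
  tech_loading <- rnorm(n_sites, 0, 1)

  make_depot <- function(cohort, depot) {
    pp <- participants[participants$cohort == cohort, ]
    nloc <- nrow(pp)
    eff <- if (depot == "subq") eff_subq else eff_visc
    tech_score <- rnorm(nloc)
    d_loc <- dos[, pp$participant_id, drop = FALSE]
    mq <- site_mqtl_beta * 0
    mq[!is.na(site_mqtl_snp)] <- site_mqtl_beta[!is.na(site_mqtl_snp)]
    mqtl_term <- matrix(0, n_sites, nloc)
    planted <- which(!is.na(site_mqtl_snp))
    mqtl_term[planted, ] <- site_mqtl_beta[planted] *
      d_loc[site_mqtl_snp[planted], , drop = FALSE]
    # noise on the logit-latent scale: beta-scale sd ~ noise_sd mid-range,
    # tapering towards the boundaries as in real array data
    lat <- qlogis(pmin(pmax(base, 1e-4), 1 - 1e-4))
    lat_sd <- noise_sd / pmax(base * (1 - base), 0.08)
    b <- plogis(matrix(lat, n_sites, nloc) +
                  matrix(rnorm(n_sites * nloc, 0, lat_sd), n_sites, nloc)) +
      outer(eff, pp$group) +
      mqtl_term +
      cfg$batch_sd * outer(tech_loading, tech_score)
    overflow <- mean(b < 0 | b > 1)
    if (overflow > 0.01)
      warning(sprintf("%.1f%% of simulated betas clamped to [0,1] (%d draws)",
                      100 * overflow, sum(b < 0 | b > 1)))
    b <- pmin(pmax(b, 0), 1)
    rownames(b) <- sites$site_id
    sid <- paste(pp$participant_id, depot, sep = "_")
    colnames(b) <- sid
    ctrl <- outer(rnorm(60, 5, 1), tech_score) + matrix(rnorm(60 * nloc, 0, 0.3), 60)
    colnames(ctrl) <- sid
    sheet <- data.frame(sample_id = sid, cohort = cohort, depot = depot,
                        participant_id = pp$participant_id, group = pp$group,
                        age = pp$age, sex = pp$sex, ethnicity = pp$ethnicity,
                        stringsAsFactors = FALSE)
    list(m = meth_matrix(b, sites$chrom, sites$pos, sheet), controls = ctrl)
  }

  meth <- list(disc_subq = make_depot("discovery", "subq"),
               disc_visc = make_depot("discovery", "visc"),
               repl_subq = make_depot("replication", "subq"),
               repl_visc = make_depot("replication", "visc"))
  controls <- lapply(meth, `[[`, "controls")
  meth <- lapply(meth, `[[`, "m")

  # expression for the replication cohort, both depots, with participant
  # random intercepts; planted methylation->expression and mediation links
  repl <- participants[participants$cohort == "replication", ]
  esheet <- rbind(meth$repl_subq$sample_sheet, meth$repl_visc$sample_sheet)
  n_es <- nrow(esheet)
  u <- rnorm(nrow(repl), 0, cfg$participant_sd)
  names(u) <- repl$participant_id
  gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  a_g <- rnorm(cfg$n_genes, log(200), 1)
  logmu <- matrix(a_g, cfg$n_genes, n_es) +
    matrix(u[esheet$participant_id], cfg$n_genes, n_es, byrow = TRUE)

  # mediation triples: TF latent drives its sentinel's methylation and the
  # target, partially through methylation
  med_pool <- setdiff(diff_idx, mqtl_site_idx)
  n_med <- min(cfg$n_mediation, cfg$n_genes %/% 10, length(med_pool))
  med_sites <- med_pool[sample.int(length(med_pool), n_med)]
  med_tf <- sample(cfg$n_genes, n_med)
  med_target <- sample(setdiff(seq_len(cfg$n_genes), med_tf), n_med)
  tf_latent <- matrix(rnorm(n_med * n_es, 0, 1), n_med, n_es)
  repl_cols_subq <- match(paste(esheet$participant_id, "subq", sep = "_"),
                          colnames(meth$repl_subq$betas))
  get_meth <- function(site_row, j) {
    dep <- esheet$depot[j]
    mm <- if (dep == "subq") meth$repl_subq else meth$repl_visc
    mm$betas[site_row, paste0(esheet$participant_id[j], "_", dep)]
  }
  for (k in seq_len(n_med)) {
    srow <- med_sites[k]
    for (j in seq_len(n_es)) {
      dep <- esheet$depot[j]
      mm_name <- if (dep == "subq") "repl_subq" else "repl_visc"
      col <- paste0(esheet$participant_id[j], "_", dep)
      newv <- min(max(meth[[mm_name]]$betas[srow, col] +
                        cfg$mediation_paths[["tf_meth"]] * tf_latent[k, j], 0), 1)
      meth[[mm_name]]$betas[srow, col] <- newv
    }
    mvals <- vapply(seq_len(n_es), function(j) get_meth(srow, j), 0)
    # path coefficients are defined on the log2-expression scale the
    # downstream models fit; natural-log means are scaled by ln 2
    logmu[med_target[k], ] <- logmu[med_target[k], ] +
      log(2) * (cfg$mediation_paths[["tf_target_direct"]] * tf_latent[k, ] +
                  cfg$mediation_paths[["meth_target"]] * (mvals - mean(mvals)))
    logmu[med_tf[k], ] <- a_g[med_tf[k]] + log(2) * tf_latent[k, ]
  }

  # plain methylation->expression target links on non-mediation genes
  free_genes <- setdiff(seq_len(cfg$n_genes), c(med_tf, med_target))
  link_pool <- setdiff(diff_idx, med_sites)
  n_link <- min(cfg$n_target_links, length(link_pool), length(free_genes))
  link_sites <- link_pool[sample.int(length(link_pool), n_link)]
  link_genes <- free_genes[sample.int(length(free_genes), n_link)]
  for (k in seq_along(link_sites)) {
    mvals <- vapply(seq_len(n_es), function(j) get_meth(link_sites[k], j), 0)
    logmu[link_genes[k], ] <- logmu[link_genes[k], ] +
      log(2) * cfg$target_slope * (mvals - mean(mvals))
  }

  sf <- exp(rnorm(n_es, 0, 0.3))
  counts <- matrix(rnbinom(cfg$n_genes * n_es,
                           mu = t(t(exp(logmu)) * sf), size = cfg$nb_size),
                   cfg$n_genes, n_es)
  rownames(counts) <- gene_id
  colnames(counts) <- esheet$sample_id
  expr <- expr_matrix(counts, esheet)

  geno <- geno_matrix(dos, snp_chrom, snp_pos, alle[, 1], alle[, 2])

  # mQTL reference panel: independent individuals, same SNP/effect structure,
  # no case/control or batch components
  nr <- cfg$n_ref
  ref_ids <- sprintf("R%04d", seq_len(nr))
  rdos <- matrix(0L, cfg$n_snps, nr)
  for (b in unique(block)) {
    idx <- which(block == b)
    h1 <- rbinom(nr, 1, maf[idx[1]]); h2 <- rbinom(nr, 1, maf[idx[1]])
    for (k in idx) {
      flip <- 0.03
      d1 <- ifelse(runif(nr) < flip, rbinom(nr, 1, maf[k]), h1)
      d2 <- ifelse(runif(nr) < flip, rbinom(nr, 1, maf[k]), h2)
      rdos[k, ] <- d1 + d2
    }
  }
  rownames(rdos) <- rownames(dos); colnames(rdos) <- ref_ids
  planted <- which(!is.na(site_mqtl_snp))
  rlat <- qlogis(pmin(pmax(base, 1e-4), 1 - 1e-4))
  rlat_sd <- noise_sd / pmax(base * (1 - base), 0.08)
  rb <- plogis(matrix(rlat, n_sites, nr) +
                 matrix(rnorm(n_sites * nr, 0, rlat_sd), n_sites, nr))
  if (length(planted) > 0)
    rb[planted, ] <- rb[planted, ] + site_mqtl_beta[planted] *
      rdos[site_mqtl_snp[planted], , drop = FALSE]
  rb <- pmin(pmax(rb, 0), 1)
  rownames(rb) <- sites$site_id
  colnames(rb) <- paste0(ref_ids, "_wat")
  ref_sheet <- data.frame(sample_id = colnames(rb), cohort = "reference",
                          depot = "wat", participant_id = ref_ids,
                          group = 0L, age = round(runif(nr, 30, 70)),
                          sex = 1L, ethnicity = 0L, stringsAsFactors = FALSE)
  ref <- list(meth = meth_matrix(rb, sites$chrom, sites$pos, ref_sheet),
              geno = geno_matrix(rdos, snp_chrom, snp_pos, alle[, 1], alle[, 2]))

  truth <- list(
    sites = data.frame(site_id = sites$site_id[diff_idx],
                       chrom = sites$chrom[diff_idx], pos = sites$pos[diff_idx],
                       effect_subq = eff_subq[diff_idx],
                       effect_visc = eff_visc[diff_idx],
                       depot_specific = !shared,
                       stringsAsFactors = FALSE),
    mqtl = data.frame(snp_id = rownames(dos)[mqtl_snp_idx],
                      site_id = sites$site_id[mqtl_site_idx],
                      beta = site_mqtl_beta[mqtl_site_idx],
                      maf = maf[mqtl_snp_idx], stringsAsFactors = FALSE),
    chains = chains,
    targets = data.frame(site_id = sites$site_id[link_sites],
                         gene_id = gene_id[link_genes],
                         slope = rep(cfg$target_slope, length(link_sites)),
                         stringsAsFactors = FALSE),
    mediation = data.frame(tf_gene = gene_id[med_tf],
                           site_id = sites$site_id[med_sites],
                           target_gene = gene_id[med_target],
                           tf_meth = rep(cfg$mediation_paths[["tf_meth"]], n_med),
                           meth_target = rep(cfg$mediation_paths[["meth_target"]], n_med),
                           tf_target_direct = rep(cfg$mediation_paths[["tf_target_direct"]], n_med),
                           stringsAsFactors = FALSE))
  class(truth) <- c("truth_table", "list")

  # referential integrity of planted ids
  stopifnot(all(truth$sites$site_id %in% sites$site_id),
            all(truth$mqtl$snp_id %in% rownames(dos)),
            all(truth$targets$gene_id %in% gene_id))

  list(meth = meth, controls = controls, expr = expr, geno = geno,
       ref = ref, truth = truth, sites = sites)
}

#' Simulate annotation tracks consistent with a planted truth table
#'
#' Places an "enhancer" feature so planted differential sites carry it at
#' `enhancer_fold` times the background rate, adds a CpG-island-like track,
#' wires a fraction of planted target links into a distal interaction map,
#' tiles chromosomes with TADs (with optional nested sub-domains), and lays
#' down gene models whose TSSs match the expression genes.
#'
#' @param cfg the [sim_config()] used for [simulate_cohort()].
#' @param sim the result of [simulate_cohort()].
#' @return list: `features` (GRanges, labels "enhancer"/"CGI"), `states`
#'   (GRanges segmentation of 20-kb chromatin-state tiles), `interactions`
#'   (`interaction_map`), `tads` (GRanges), `genes` (`gene_models`),
#'   `motifs` (GRanges of motif occurrences around planted mediation sites).
#' @export
simulate_annotations <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  sites <- sim$sites
  planted <- sites$site_id %in% sim$truth$sites$site_id
  p0 <- cfg$enhancer_base_rate
  p1 <- cfg$enhancer_fold * p0
  if (p1 > 1)
    stop(sprintf("requested fold unattainable: maximum achievable fold is %.2f", 1 / p0))
  in_enh <- ifelse(planted, runif(nrow(sites)) < p1, runif(nrow(sites)) < p0)
  enh <- GenomicRanges::GRanges(sites$chrom[in_enh],
                                IRanges::IRanges(pmax(1L, sites$pos[in_enh] - 100L),
                                                 sites$pos[in_enh] + 100L),
                                label = "enhancer")
  cgi_pick <- runif(nrow(sites)) < 0.12
  cgi <- GenomicRanges::GRanges(sites$chrom[cgi_pick],
                                IRanges::IRanges(pmax(1L, sites$pos[cgi_pick] - 250L),
                                                 sites$pos[cgi_pick] + 250L),
                                label = "CGI")
  features <- GenomicRanges::sort(suppressWarnings(c(enh, cgi)), ignore.strand = TRUE)

  # gene models: TSS tiled per chromosome, 3 exons + UTRs per gene
  gene_id <- rownames(sim$expr$counts)
  n_genes <- length(gene_id)
  gchrom <- sample(unique(sites$chrom), n_genes, replace = TRUE)
  gtss <- as.integer(runif(n_genes, 1e4, max(sites$pos)))
  gstrand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_df <- data.frame(gene_id = gene_id, chrom = gchrom, strand = gstrand,
                        tss = gtss, stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    s0 <- gtss[i] - 1L   # 0-based
    dirn <- if (gstrand[i] == "+") 1L else -1L
    starts <- s0 + dirn * c(0L, 2000L, 5000L) * 1L
    starts <- if (dirn == 1L) starts else starts - 800L
    data.frame(gene_id = gene_id[i], start = pmax(0L, as.integer(starts)),
               end = pmax(1L, as.integer(starts)) + 800L,
               kind = c("utr5", "exon", "utr3"), stringsAsFactors = FALSE)
  }))
  genes <- gene_models(gene_df, ex, promoter_halfwidth = 5000L)

  # distal interactions for a fraction of planted target links
  tg <- sim$truth$targets
  pick <- runif(nrow(tg)) < cfg$interaction_frac
  tpos <- sites$pos[match(tg$site_id, sites$site_id)]
  tchr <- sites$chrom[match(tg$site_id, sites$site_id)]
  inter <- data.frame(chrom = tchr[pick],
                      start = pmax(0L, tpos[pick] - 500L), end = tpos[pick] + 500L,
                      gene_id = tg$gene_id[pick], source = "capture_hic",
                      stringsAsFactors = FALSE)
  class(inter) <- c("interaction_map", "data.frame")

  # TADs tile each chromosome; optional nested sub-domains
  tads <- suppressWarnings(do.call(c, lapply(unique(sites$chrom), function(ch) {
    len <- max(sites$pos[sites$chrom == ch]) + 1e5
    edges <- unique(as.integer(seq(0, len, by = 5e5)))
    if (length(edges) < 2) edges <- c(0L, as.integer(len))
    g <- GenomicRanges::GRanges(ch, IRanges::IRanges(head(edges, -1) + 1L, tail(edges, -1)),
                                label = "tad")
    if (cfg$tad_nesting > 0) {
      inner <- do.call(c, lapply(seq_len(cfg$tad_nesting), function(d) {
        w <- GenomicRanges::width(g) %/% (2^d)
        GenomicRanges::GRanges(ch, IRanges::IRanges(GenomicRanges::start(g) + w %/% 2,
                                                    width = pmax(2L, w)),
                               label = "tad_nested")
      }))
      g <- c(g, inner)
    }
    g
  })))

  # chromatin-state segmentation: 20-kb tiles with reference-map-like labels
  states <- suppressWarnings(do.call(c, lapply(unique(sites$chrom), function(ch) {
    len <- max(sites$pos[sites$chrom == ch]) + 4e4
    edges <- unique(as.integer(seq(0, len, by = 2e4)))
    lab <- sample(c("tss_active", "enhancer_state", "transcribed",
                    "quiescent", "polycomb"),
                  length(edges) - 1, replace = TRUE,
                  prob = c(0.1, 0.15, 0.25, 0.4, 0.1))
    GenomicRanges::GRanges(ch, IRanges::IRanges(head(edges, -1) + 1L, tail(edges, -1)),
                           label = lab)
  })))

  # motif occurrences centred near planted mediation sites (21-bp motifs)
  med <- sim$truth$mediation
  mpos <- sites$pos[match(med$site_id, sites$site_id)]
  mchr <- sites$chrom[match(med$site_id, sites$site_id)]
  motifs <- GenomicRanges::GRanges(mchr,
                                   IRanges::IRanges(mpos - 10L, mpos + 10L),
                                   strand = sample(c("+", "-"), nrow(med), replace = TRUE),
                                   label = "motif1", sentinel = med$site_id)

  list(features = features, states = states, interactions = inter,
       tads = tads, genes = genes, motifs = motifs)
}

#' Simulate GWAS outcome summary statistics from planted causal chains
#'
#' For forward chains the SNP effect on the outcome equals the product of the
#' SNP-to-methylation and methylation-to-phenotype coefficients plus sampling
#' noise at the stated GWAS size; reverse chains give the SNP its direct
#' phenotype effect (methylation is downstream); all other SNPs receive pure
#' noise. An optional constant pleiotropy offset is added to every chain SNP
#' to exercise the Egger intercept.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param geno the simulated `geno_matrix` (for alleles and MAF).
#' @param n_gwas GWAS sample size (>= 100).
#' @param seed RNG seed.
#' @param pleiotropy constant outcome offset added to chain SNPs.
#' @return `gwas_summary` data.frame over all SNPs in `geno`.
#' @export
simulate_gwas_from_chain <- function(truth, geno, n_gwas, seed, pleiotropy = 0) {
  if (n_gwas < 100) stop("n_gwas < 100 gives unstable standard errors")
  set.seed(seed)
  snp <- rownames(geno$dosages)
  maf <- pmax(geno$maf, 0.01)
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_gwas)
  beta <- rnorm(length(snp), 0, se)
  ch <- truth$chains
  idx <- match(ch$snp_id, snp)
  mu <- ifelse(ch$direction == "forward",
               ch$snp_cpg_beta * ch$cpg_phen_beta,
               ch$snp_phen_direct)
  beta[idx] <- rnorm(nrow(ch), mu + pleiotropy, se[idx])
  p <- 2 * pnorm(-abs(beta / se))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(snp = snp, effect_allele = geno$effect_allele,
                    other_allele = geno$other_allele,
                    beta = beta, se = se, p = p, n = n_gwas,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Write a truth table to TSV files
#' @param truth truth table; `dir` output directory.
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth))
    data.table::fwrite(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE)
  invisible(dir)
}
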