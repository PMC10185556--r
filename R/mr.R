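# Instrument discovery (cis-mQTL scan), LD clumping, allele harmonisation and
# two-sample Mendelian randomisation with heterogeneity, pleiotropy and
# Steiger directionality diagnostics.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Cis-mQTL scan around a methylation site
#'
#' Each SNP within `window` bp of the site (same chromosome) is tested by OLS
#' of methylation beta on effect-allele dosage, optionally after covariate
#' adjustment. Strand-ambiguous palindromic SNPs (A/T or C/G) with MAF above
#' `pal_maf` are removed before testing.
#'
#' @param g `geno_matrix` (samples = participants).
#' @param m `meth_matrix`; methylation samples are matched to genotype
#'   participants via the sample sheet's `participant_id`.
#' @param site site id in `m`.
#' @param window cis window half-width (default 500000).
#' @param covars optional covariate matrix aligned to methylation samples.
#' @param pal_maf palindromic MAF exclusion threshold (default 0.42).
#' @return data.frame of class `mqtl_records`: snp_id, site_id, beta, se, p,
#'   r2, distance, effect_allele, other_allele, maf, n.
#' @export
mqtl_scan <- function(g, m, site, window = 500000L, covars = NULL,
                      pal_maf = 0.42) {
  srow <- match(site, rownames(m$betas))
  if (is.na(srow)) stop("site ", site, " not in methylation matrix")
  ch <- m$chrom[srow]; pos <- m$pos[srow]
  dist <- ifelse(g$chrom == ch, g$pos - pos, NA_integer_)
  inwin <- !is.na(dist) & abs(dist) <= window
  pal_drop <- .is_palindromic(g$effect_allele, g$other_allele) & g$maf > pal_maf
  keep <- which(inwin & !pal_drop)
  if (length(keep) == 0) {
    message("no in-window SNPs for site ", site)
    out <- data.frame(snp_id = character(), site_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      r2 = numeric(), distance = integer(),
                      effect_allele = character(), other_allele = character(),
                      maf = numeric(), n = integer())
    class(out) <- c("mqtl_records", "data.frame")
    return(out)
  }
  pid <- m$sample_sheet$participant_id
  gidx <- match(pid, colnames(g$dosages))
  y <- m$betas[srow, ]
  if (!is.null(covars)) {
    keep_s <- !is.na(y) & !is.na(gidx) & !apply(is.na(as.matrix(covars)), 1, any)
  } else keep_s <- !is.na(y) & !is.na(gidx)
  y <- y[keep_s]; gidx <- gidx[keep_s]
  C <- if (!is.null(covars)) as.matrix(covars)[keep_s, , drop = FALSE] else NULL
  rows <- lapply(keep, function(sn) {
    d <- g$dosages[sn, gidx]
    X <- cbind(1, dosage = d)
    if (!is.null(C)) X <- cbind(X, C)
    if (qr(X)$rank < ncol(X)) return(NULL)   # monomorphic SNP
    f <- lm.fit(X, y)
    df <- length(y) - ncol(X)
    s2 <- sum(f$residuals^2) / df
    xtxinv <- chol2inv(chol(crossprod(X)))
    beta <- f$coefficients[["dosage"]]
    se <- sqrt(s2 * xtxinv[2, 2])
    tv <- beta / se
    r2 <- tv^2 / (tv^2 + df)
    data.frame(snp_id = rownames(g$dosages)[sn], site_id = site, beta = beta,
               se = se, p = pmin(pmax(2 * pt(-abs(tv), df), .Machine$double.xmin), 1),
               r2 = r2, distance = dist[sn],
               effect_allele = g$effect_allele[sn], other_allele = g$other_allele[sn],
               maf = g$maf[sn], n = length(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tested") <- length(keep)
  class(out) <- c("mqtl_records", "data.frame")
  out
}

#' Greedy LD clumping of mQTL records
#'
#' Records are visited in order of ascending p; a SNP is retained iff its
#' dosage r-squared with every already-retained SNP is below `r2_max`.
#' Monomorphic SNPs (undefined correlation) are treated as independent and
#' flagged.
#'
#' @param records `mqtl_records`.
#' @param g `geno_matrix` providing the dosages for LD.
#' @param r2_max exclusion threshold (default 0.01).
#' @return clumped `mqtl_records` (attribute `flagged_monomorphic` lists any).
#' @export
ld_clump <- function(records, g, r2_max = 0.01) {
  if (nrow(records) <= 1 || r2_max >= 1) return(records)  # bound >= 1 is a no-op
  ord <- order(records$p, records$snp_id)
  kept <- integer(0)
  mono <- character(0)
  D <- g$dosages[records$snp_id, , drop = FALSE]
  v <- apply(D, 1, var)
  for (i in ord) {
    if (v[i] == 0) { mono <- c(mono, records$snp_id[i]); kept <- c(kept, i); next }
    ok <- TRUE
    for (j in kept) {
      if (v[j] == 0) next
      r2 <- cor(D[i, ], D[j, ])^2
      if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- records[sort(kept), , drop = FALSE]
  attr(out, "flagged_monomorphic") <- mono
  class(out) <- c("mqtl_records", "data.frame")
  out
}

#' Harmonise an outcome GWAS row to an exposure instrument
#'
#' Flips the outcome beta when the outcome's effect allele matches the
#' exposure's other allele (directly or via strand complement). Alleles that
#' cannot be reconciled raise an error.
#'
#' @param instr one `mqtl_records` row (effect_allele/other_allele columns).
#' @param outcome one `gwas_summary` row.
#' @return the outcome row with beta aligned to the exposure effect allele.
#' @export
harmonise_outcome <- function(instr, outcome) {
  ea <- instr$effect_allele; oa <- instr$other_allele
  oe <- outcome$effect_allele; oo <- outcome$other_allele
  same <- (oe == ea & oo == oa)
  flip <- (oe == oa & oo == ea)
  if (!same && !flip) {   # try strand complement
    oe2 <- .complement[oe]; oo2 <- .complement[oo]
    same <- (oe2 == ea & oo2 == oa)
    flip <- (oe2 == oa & oo2 == ea)
  }
  if (!same && !flip)
    stop(sprintf("cannot harmonise alleles for %s: exposure %s/%s vs outcome %s/%s",
                 outcome$snp, ea, oa, outcome$effect_allele, outcome$other_allele))
  if (flip) {
    outcome$beta <- -outcome$beta
    tmp <- outcome$effect_allele
    outcome$effect_allele <- outcome$other_allele
    outcome$other_allele <- tmp
  }
  outcome
}

.mr_row <- function(site, trait, method, beta, se, n_snps,
                    Q = NA_real_, Q_p = NA_real_,
                    egger_intercept = NA_real_, egger_intercept_p = NA_real_) {
  p <- pmin(pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin), 1)
  data.frame(site_id = site, trait = trait, method = method, beta = beta,
             se = se, p = p, n_snps = n_snps, cochran_Q = Q, Q_p = Q_p,
             egger_intercept = egger_intercept,
             egger_intercept_p = egger_intercept_p, stringsAsFactors = FALSE)
}

#' Wald-ratio causal estimate from a single instrument
#'
#' beta = beta_outcome / beta_exposure with first-order standard error
#' se_outcome / |beta_exposure|. The outcome row must already be harmonised.
#'
#' @param instr one `mqtl_records` row.
#' @param outcome harmonised `gwas_summary` row.
#' @param trait trait label.
#' @return one-row `mr_result` data.frame.
#' @export
wald_ratio <- function(instr, outcome, trait = "trait") {
  if (abs(instr$beta) < 1e-12) stop("exposure effect too close to zero for a Wald ratio")
  beta <- outcome$beta / instr$beta
  se <- outcome$se / abs(instr$beta)
  .mr_row(instr$site_id, trait, "wald", beta, se, 1L)
}

#' Inverse-variance-weighted MR over multiple instruments
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights 1 / se_outcome^2 (equivalently, the precision-weighted mean of
#' per-SNP Wald ratios). Cochran's Q measures instrument heterogeneity;
#' under `effects = "random"` the standard error is inflated by
#' sqrt(Q / (n - 1)) floored at 1 (multiplicative random-effects model).
#'
#' @param instrs `mqtl_records` (>= 2 rows).
#' @param outcomes harmonised `gwas_summary` rows aligned to `instrs`.
#' @param effects "fixed" or "random".
#' @param trait label.
#' @return one-row `mr_result` data.frame.
#' @export
ivw_mr <- function(instrs, outcomes, effects = c("fixed", "random"),
                   trait = "trait") {
  effects <- match.arg(effects)
  if (nrow(instrs) < 2) stop("need >= 2 instruments; use wald_ratio for a single SNP")
  w <- 1 / outcomes$se^2
  bx <- instrs$beta; by <- outcomes$beta
  bhat <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  Q <- sum(w * (by - bhat * bx)^2)
  dfq <- nrow(instrs) - 1
  if (effects == "random") se <- se * max(1, sqrt(Q / dfq))
  .mr_row(instrs$site_id[1], trait, "ivw", bhat, se, nrow(instrs),
          Q = Q, Q_p = pmin(1, stats::pchisq(Q, dfq, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' after orienting all exposure effects non-negative; the slope is the causal
#' estimate and the intercept (with its p-value) tests directional horizontal
#' pleiotropy. Requires >= 3 instruments.
#'
#' @param instrs,outcomes,trait as [ivw_mr()].
#' @return one-row `mr_result` data.frame.
#' @export
egger_mr <- function(instrs, outcomes, trait = "trait") {
  if (nrow(instrs) < 3) stop("MR-Egger needs >= 3 instruments")
  flip <- sign(instrs$beta)
  flip[flip == 0] <- 1
  bx <- instrs$beta * flip; by <- outcomes$beta * flip
  w <- 1 / outcomes$se^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  .mr_row(instrs$site_id[1], trait, "egger", sm["bx", 1], sm["bx", 2],
          nrow(instrs),
          egger_intercept = sm["(Intercept)", 1],
          egger_intercept_p = sm["(Intercept)", 4])
}

#' Steiger directionality test
#'
#' Compares the variance the instrument explains in the exposure
#' (SNP-methylation r2) with that in the outcome (SNP-phenotype r2) via
#' Fisher z-transformed correlations for independent samples. Direction is
#' exposure-to-outcome iff r2_exposure > r2_outcome.
#'
#' @param r2_exposure,n_exposure instrument r2 and sample size on the
#'   exposure side.
#' @param r2_outcome,n_outcome same on the outcome side.
#' @return list: direction ("exposure->outcome" or "outcome->exposure"), z, p.
#' @export
steiger_test <- function(r2_exposure, n_exposure, r2_outcome, n_outcome) {
  stopifnot(r2_exposure >= 0, r2_outcome >= 0, n_exposure >= 4, n_outcome >= 4)
  if (r2_exposure >= 1 || r2_outcome >= 1) stop("r2 = 1 is degenerate")
  z <- (atanh(sqrt(r2_exposure)) - atanh(sqrt(r2_outcome))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  p <- pmin(pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), 1)
  list(direction = if (r2_exposure > r2_outcome) "exposure->outcome"
       else "outcome->exposure", z = z, p = p)
}

# outcome r2 from GWAS summary: r2 = t^2 / (t^2 + n - 2)
.gwas_r2 <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Full per-sentinel two-sample MR pipeline
#'
#' For each sentinel and trait: cis-mQTL scan, Bonferroni instrument gate
#' (p < 0.05 / number of in-window SNPs tested for that sentinel), LD clumping
#' at r2 < `clump_r2`, harmonisation, Wald ratio (1 instrument) or IVW
#' (several), Steiger directionality per sentinel (precision-weighted average
#' of per-instrument r2), then BH q-values across all sentinel-trait tests
#' (separate families for the MR and Steiger p-values). A sentinel-trait pair
#' is flagged causal iff q_MR < `q_thresh`, q_Steiger < `q_thresh` and the
#' direction is exposure-to-outcome. A correlated-instrument sensitivity
#' re-run (clumping at r2 < `sens_r2`) adds IVW and Egger rows where >= 3
#' instruments survive.
#'
#' @param sentinels data.frame with sentinel_id (site ids in `m`).
#' @param g `geno_matrix`; `m` `meth_matrix`; `covars` optional.
#' @param m methylation matrix used for the mQTL scan.
#' @param gwas named list of `gwas_summary` tables (one per trait).
#' @param covars covariates for the mQTL scan.
#' @param window cis window (default 500000).
#' @param clump_r2 primary clumping threshold (default 0.01).
#' @param sens_r2 sensitivity clumping threshold (default 0.8).
#' @param q_thresh FDR gate (default 0.01).
#' @param instrument_alpha instrument-selection significance before the
#'   Bonferroni denominator (default 0.05).
#' @param fdr_family "separate" (default) corrects MR and Steiger p-values in
#'   their own BH families; "joint" pools them into one family.
#' @return list: `results` (mr_result table with steiger columns, q-values and
#'   `causal` flag), `sensitivity` (IVW/Egger table), `untestable` (sentinels
#'   with no surviving instruments).
#' @export
mr_pipeline <- function(sentinels, g, m, gwas, covars = NULL,
                        window = 500000L, clump_r2 = 0.01, sens_r2 = 0.8,
                        q_thresh = 0.01, instrument_alpha = 0.05,
                        fdr_family = c("separate", "joint")) {
  fdr_family <- match.arg(fdr_family)
  res <- list(); sens <- list(); untestable <- character(0)
  for (i in seq_len(nrow(sentinels))) {
    sid <- sentinels$sentinel_id[i]
    rec <- mqtl_scan(g, m, sid, window = window, covars = covars)
    n_tested <- attr(rec, "n_tested")
    if (is.null(n_tested)) n_tested <- nrow(rec)
    gate <- rec[rec$p < instrument_alpha / max(n_tested, 1), , drop = FALSE]
    if (nrow(gate) == 0) { untestable <- c(untestable, sid); next }
    instr <- ld_clump(gate, g, r2_max = clump_r2)
    for (trait in names(gwas)) {
      gs <- gwas[[trait]]
      oidx <- match(instr$snp_id, gs$snp)
      ok <- !is.na(oidx)
      if (!any(ok)) next
      ii <- instr[ok, , drop = FALSE]
      oo <- do.call(rbind, lapply(seq_len(nrow(ii)), function(k)
        harmonise_outcome(ii[k, ], gs[oidx[ok][k], ])))
      row <- if (nrow(ii) == 1) wald_ratio(ii, oo, trait)
      else ivw_mr(ii, oo, effects = "fixed", trait = trait)
      w <- 1 / oo$se^2
      r2_exp <- sum(w * ii$r2) / sum(w)
      r2_out <- sum(w * .gwas_r2(oo$beta, oo$se, oo$n)) / sum(w)
      st <- steiger_test(r2_exp, ii$n[1], r2_out, oo$n[1])
      row$steiger_direction <- st$direction
      row$steiger_p <- st$p
      res[[length(res) + 1]] <- row
      # correlated-instrument sensitivity set
      sinstr <- ld_clump(gate, g, r2_max = sens_r2)
      soidx <- match(sinstr$snp_id, gs$snp)
      sok <- !is.na(soidx)
      if (sum(sok) >= 3) {
        si <- sinstr[sok, , drop = FALSE]
        so <- do.call(rbind, lapply(seq_len(nrow(si)), function(k)
          harmonise_outcome(si[k, ], gs[soidx[sok][k], ])))
        sens[[length(sens) + 1]] <- ivw_mr(si, so, effects = "random", trait = trait)
        sens[[length(sens) + 1]] <- egger_mr(si, so, trait = trait)
      }
    }
  }
  if (length(res) == 0)
    return(list(results = NULL, sensitivity = NULL, untestable = untestable))
  results <- do.call(rbind, res)
  if (fdr_family == "separate") {
    results$q <- bh_fdr(results$p)
    results$q_steiger <- bh_fdr(results$steiger_p)
  } else {
    qq <- bh_fdr(c(results$p, results$steiger_p))
    results$q <- qq[seq_len(nrow(results))]
    results$q_steiger <- qq[nrow(results) + seq_len(nrow(results))]
  }
  results$causal <- results$q < q_thresh & results$q_steiger < q_thresh &
    results$steiger_direction == "exposure->outcome"
  sensitivity <- if (length(sens) > 0) do.call(rbind, sens) else NULL
  list(results = results, sensitivity = sensitivity, untestable = untestable)
}

#' Proxy SNP lookup by maximum dosage LD
#'
#' Finds the candidate SNP within `window` bp with the highest dosage
#' r-squared with the target (itself qualifying at r2 = 1 if present), subject
#' to r2 >= `r2_min`. The aligned allele is the candidate's effect allele when
#' the dosage correlation is positive, its other allele when negative.
#'
#' @param snp_id target SNP id (must be genotyped in `g`).
#' @param g `geno_matrix` acting as reference panel.
#' @param r2_min minimum r-squared (default 0.8).
#' @param window search window in bp (default 500000).
#' @param exclude_self set TRUE to disallow returning the target itself.
#' @return list(proxy_id, r2, aligned_allele) or NULL when nothing qualifies.
#' @export
proxy_lookup <- function(snp_id, g, r2_min = 0.8, window = 500000L,
                         exclude_self = FALSE) {
  ti <- match(snp_id, rownames(g$dosages))
  if (is.na(ti)) stop("target SNP not genotyped")
  cand <- which(g$chrom == g$chrom[ti] & abs(g$pos - g$pos[ti]) <= window)
  if (exclude_self) cand <- setdiff(cand, ti)
  if (length(cand) == 0) { message("no candidate proxies"); return(NULL) }
  target <- g$dosages[ti, ]
  r <- vapply(cand, function(j) {
    suppressWarnings(cor(target, g$dosages[j, ]))
  }, 0)
  r[is.na(r)] <- 0
  best <- which.max(r^2)
  if (r[best]^2 < r2_min) { message("best proxy r2 below threshold"); return(NULL) }
  j <- cand[best]
  list(proxy_id = rownames(g$dosages)[j], r2 = r[best]^2,
       aligned_allele = if (r[best] >= 0) g$effect_allele[j] else g$other_allele[j])
}
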