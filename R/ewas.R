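# Per-site case/control association, technical covariates, meta-analysis,
# multiple testing and replication gating.

#' Remove excluded probes from a methylation matrix
#'
#' Mirrors array practice of dropping cross-hybridising probes and probes with
#' common variants in the probe sequence; the exclusion list is consumed as
#' input, not derived here.
#'
#' @param m `meth_matrix`.
#' @param exclusions character vector of site ids to drop.
#' @return filtered `meth_matrix`; a message reports removal counts and any
#'   exclusion ids not present.
#' @export
filter_sites <- function(m, exclusions) {
  exclusions <- unique(exclusions)
  if (length(exclusions) == 0) {
    warning("empty exclusion list; matrix passed through unchanged")
    return(m)
  }
  present <- exclusions %in% rownames(m$betas)
  if (any(!present))
    message(sum(!present), " exclusion ids not present in matrix; ignored")
  keep <- !(rownames(m$betas) %in% exclusions)
  message(sum(!keep), " sites removed, ", sum(keep), " remain")
  meth_matrix(m$betas[keep, , drop = FALSE], m$chrom[keep], m$pos[keep],
              m$sample_sheet)
}

#' Quantile normalise a methylation matrix across samples
#'
#' Each sample's sorted values are replaced by the cross-sample mean of order
#' statistics; tied values receive the mean of the reference values their rank
#' range spans. Samples with missing values are mapped through interpolated
#' reference quantiles so every sample shares one target distribution.
#'
#' @param m `meth_matrix` with >= 2 samples.
#' @return quantile-normalised `meth_matrix`.
#' @export
quantile_normalize <- function(m) {
  x <- m$betas
  if (ncol(x) < 2) stop("need >= 2 samples to quantile normalise")
  if (any(colSums(!is.na(x)) == 0)) stop("all-missing sample column")
  n <- nrow(x)
  # reference: mean of per-sample quantiles on a common grid
  p <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  qs <- apply(x, 2, function(col) {
    v <- sort(col[!is.na(col)])
    k <- length(v)
    if (k == n) v else approx(x = if (k > 1) (seq_len(k) - 1) / (k - 1) else 0.5,
                              y = v, xout = p, rule = 2)$y
  })
  ref <- rowMeans(qs)
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    ok <- !is.na(col)
    k <- sum(ok)
    r <- rank(col[ok], ties.method = "average")
    # rank -> reference quantile; averaged ranks land between grid points
    pr <- if (k > 1) (r - 1) / (k - 1) else 0.5
    out[ok, j] <- approx(x = p, y = ref, xout = pr, rule = 2)$y
  }
  m$betas <- pmin(pmax(out, 0), 1)
  m
}

#' Principal components of control-probe intensities
#'
#' PCA of the control-probe intensity matrix summarises technical variation
#' (staining, extension, bisulphite conversion, ...); the leading components
#' are used as covariates in the association models.
#'
#' @param controls complete numeric matrix, control probes x samples.
#' @param var_target cumulative explained-variance target (default 0.95).
#' @return matrix of centred PC scores (samples x k), k the smallest number of
#'   components reaching `var_target`; attribute `explained` carries the
#'   per-component variance fractions.
#' @export
control_probe_pcs <- function(controls, var_target = 0.95) {
  if (ncol(controls) < 2) stop("need >= 2 samples")
  if (anyNA(controls)) stop("control intensities must be complete")
  pc <- prcomp(t(controls), center = TRUE, scale. = FALSE)
  vfrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(vfrac) >= var_target)[1]
  if (is.na(k)) k <- length(vfrac)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "explained") <- vfrac
  scores
}

# design matrix with rank check; names collinear columns on failure
.design <- function(pheno, covars, n) {
  X <- cbind(`(Intercept)` = 1, pheno = pheno)
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    if (is.null(colnames(covars)))
      colnames(covars) <- paste0("covar", seq_len(ncol(covars)))
    X <- cbind(X, covars)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("perfect collinearity among covariates: ", paste(drop, collapse = ", "))
  }
  X
}

#' Per-site linear association of methylation with a binary phenotype
#'
#' OLS of beta value on case/control status plus covariates, one fit per site.
#' The phenotype coefficient is the case-minus-control methylation difference
#' in fraction units. Sites with missing betas are fit by listwise deletion;
#' sites with fewer than `rank + 3` complete observations are skipped and
#' flagged.
#'
#' @param m `meth_matrix`.
#' @param pheno 0/1 vector aligned to samples.
#' @param covars optional numeric matrix aligned to samples.
#' @param cohort cohort label stored with the results.
#' @return data.frame of class `assoc_result`: site_id, effect, se, p, q
#'   (BH), n, direction, cohort.
#' @export
site_association <- function(m, pheno, covars = NULL, cohort = "cohort") {
  stopifnot(all(pheno %in% c(0, 1)), length(pheno) == ncol(m$betas))
  X <- .design(pheno, covars, ncol(m$betas))
  Y <- m$betas
  p_eff <- ncol(X)
  n_sites <- nrow(Y)
  effect <- se <- rep(NA_real_, n_sites)
  nobs <- integer(n_sites)
  complete <- !apply(is.na(Y), 1, any)

  if (any(complete)) {
    XtXinv <- chol2inv(chol(crossprod(X)))
    H <- X %*% XtXinv            # n x p
    B <- Y[complete, , drop = FALSE] %*% H          # coefficients per site
    fitted <- B %*% t(X)
    res <- Y[complete, , drop = FALSE] - fitted
    df <- ncol(Y) - p_eff
    sigma2 <- rowSums(res^2) / df
    effect[complete] <- B[, 2]
    se[complete] <- sqrt(sigma2 * XtXinv[2, 2])
    nobs[complete] <- ncol(Y)
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) - p_eff < 3) { nobs[i] <- sum(ok); next }
    f <- lm.fit(X[ok, , drop = FALSE], Y[i, ok])
    if (f$rank < p_eff) next
    r <- f$residuals
    s2 <- sum(r^2) / (sum(ok) - p_eff)
    xtxinv <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
    effect[i] <- f$coefficients["pheno"]
    se[i] <- sqrt(s2 * xtxinv[2, 2])
    nobs[i] <- sum(ok)
  }
  tstat <- effect / se
  dfv <- nobs - p_eff
  p <- 2 * pt(-abs(tstat), pmax(dfv, 1))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(site_id = rownames(Y), effect = effect, se = se, p = p,
                    q = NA_real_, n = nobs,
                    direction = sign(effect), cohort = cohort,
                    skipped = is.na(effect), stringsAsFactors = FALSE)
  out$q[!out$skipped] <- bh_fdr(out$p[!out$skipped])
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Inverse-variance-weighted fixed-effects meta-analysis of two cohorts
#'
#' Combines per-site effects with weights 1/se^2 and reports Cochran's Q and
#' I-squared heterogeneity. Sites present in only one cohort are excluded with
#' a message.
#'
#' @param a,b `assoc_result` tables from two cohorts.
#' @return data.frame of class `meta_result`: site_id, effect, se, p, q,
#'   Q, I2, effect_a/effect_b, p_a/p_b.
#' @export
ivw_meta <- function(a, b) {
  a <- a[!a$skipped, ]; b <- b[!b$skipped, ]
  common <- intersect(a$site_id, b$site_id)
  dropped <- length(union(a$site_id, b$site_id)) - length(common)
  if (dropped > 0) message(dropped, " sites present in only one cohort excluded")
  ia <- match(common, a$site_id); ib <- match(common, b$site_id)
  wa <- 1 / a$se[ia]^2; wb <- 1 / b$se[ib]^2
  eff <- (wa * a$effect[ia] + wb * b$effect[ib]) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  Q <- wa * (a$effect[ia] - eff)^2 + wb * (b$effect[ib] - eff)^2
  I2 <- pmax(0, (Q - 1) / Q)
  p <- 2 * pnorm(-abs(eff / se))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(site_id = common, effect = eff, se = se, p = p,
                    q = bh_fdr(p), Q = Q, I2 = I2,
                    effect_a = a$effect[ia], effect_b = b$effect[ib],
                    p_a = a$p[ia], p_b = b$p[ib], stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#' @param p vector of p-values in (0,1].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Replication gating of discovery associations
#'
#' A site passes iff (i) discovery FDR < `q_thresh`, (ii) replication FDR <
#' `q_thresh` with the same direction of effect, and (iii) combined
#' fixed-effects p < `p_meta`. Also returns the direction-consistency count
#' (k consistent of n discovery-significant) feeding the binomial sign test.
#'
#' @param disc,repl `assoc_result` for discovery and replication.
#' @param meta `meta_result` combining the two.
#' @param q_thresh FDR gate (default 0.01).
#' @param p_meta combined-p gate (default 1e-7, epigenome-wide significance).
#' @return list: `sites` (character ids passing all gates), `k` and `n` for
#'   the sign test, `table` (per-site gate breakdown for discovery-significant
#'   sites).
#' @export
replication_gate <- function(disc, repl, meta, q_thresh = 0.01, p_meta = 1e-7) {
  d <- disc[!disc$skipped & disc$q < q_thresh, ]
  ir <- match(d$site_id, repl$site_id)
  im <- match(d$site_id, meta$site_id)
  consistent <- !is.na(ir) & sign(d$effect) == sign(repl$effect[ir])
  pass <- consistent & repl$q[ir] < q_thresh & !is.na(im) & meta$p[im] < p_meta
  pass[is.na(pass)] <- FALSE
  list(sites = d$site_id[pass],
       k = sum(consistent, na.rm = TRUE), n = nrow(d),
       table = data.frame(site_id = d$site_id, q_disc = d$q,
                          q_repl = repl$q[ir], consistent = consistent,
                          p_meta = meta$p[im], pass = pass,
                          stringsAsFactors = FALSE))
}

#' Sensitivity re-fit with additional covariates
#'
#' Fits the association model without and with extra covariates (e.g. genetic
#' principal components, contaminating-cell expression PCs) and reports the
#' per-site effect attenuation 1 - beta_with / beta_without.
#'
#' @param m,pheno,covars as [site_association()].
#' @param extra additional covariate matrix aligned to samples.
#' @param cohort label.
#' @return list: `without`, `with` (both `assoc_result`), `attenuation`
#'   (named numeric per site).
#' @export
sensitivity_refit <- function(m, pheno, covars = NULL, extra, cohort = "cohort") {
  base_fit <- site_association(m, pheno, covars, cohort = cohort)
  full_cov <- if (is.null(covars)) as.matrix(extra) else cbind(covars, extra)
  full_fit <- site_association(m, pheno, full_cov, cohort = cohort)
  att <- 1 - full_fit$effect / base_fit$effect
  names(att) <- base_fit$site_id
  list(without = base_fit, with = full_fit, attenuation = att)
}
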