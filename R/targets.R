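# Target-gene assignment (genic / functional-interaction / TAD tiers),
# methylation-expression association with a participant random intercept,
# and differential-expression enrichment of targets.

#' Remove nested TADs, keeping the largest domains
#'
#' Drops every interval strictly contained in another (proper subset);
#' partial overlaps are retained, exact duplicates collapse to one record.
#' Idempotent.
#'
#' @param raw GRanges of called TADs.
#' @return GRanges with no interval contained in another; attribute `removed`
#'   carries the dropped intervals.
#' @export
merge_tads <- function(raw) {
  gr <- unique(raw)
  keep <- rep(TRUE, length(gr))
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    idx <- which(as.character(GenomicRanges::seqnames(gr)) == ch)
    s <- GenomicRanges::start(gr)[idx]; e <- GenomicRanges::end(gr)[idx]
    o <- order(s, -e)
    maxend <- -Inf
    for (i in o) {
      if (e[i] <= maxend) keep[idx[i]] <- FALSE else maxend <- e[i]
    }
  }
  out <- gr[keep]
  attr(out, "removed") <- gr[!keep]
  out
}

#' Assign sentinels to candidate target genes by the three-tier rule
#'
#' Tier "genic": the sentinel overlaps an exon, UTR or the promoter window
#' (TSS +/- promoter half-width) of a gene. Tier "functional" (only when no
#' genic assignment): the sentinel falls inside a distal interaction interval
#' connected to a gene. Tier "tad" (only when both earlier tiers are empty):
#' every gene whose TSS lies inside a TAD containing the sentinel. Tiers are
#' exclusive per sentinel.
#'
#' @param sentinels data.frame: sentinel_id, chrom, pos.
#' @param genes `gene_models`.
#' @param interactions `interaction_map`.
#' @param tads GRanges (after [merge_tads()]).
#' @return data.frame of class `target_assignment`: sentinel_id, gene_id,
#'   tier, evidence.
#' @export
assign_targets <- function(sentinels, genes, interactions, tads) {
  g <- genes$gene
  hw <- genes$promoter_halfwidth
  rows <- list()
  for (i in seq_len(nrow(sentinels))) {
    sid <- sentinels$sentinel_id[i]
    ch <- sentinels$chrom[i]; pos <- sentinels$pos[i]; p0 <- pos - 1L
    if (!ch %in% c(g$chrom, interactions$chrom,
                   as.character(GenomicRanges::seqnames(tads)))) {
      message("sentinel ", sid, " on chromosome absent from annotations; unassigned")
      next
    }
    # tier 1: genic
    onchr <- g[g$chrom == ch, , drop = FALSE]
    hits <- character(0); ev <- character(0)
    if (nrow(onchr) > 0) {
      prom <- abs(pos - onchr$tss) <= hw
      for (j in which(prom)) { hits <- c(hits, onchr$gene_id[j]); ev <- c(ev, "promoter") }
      ex <- genes$exons[genes$exons$gene_id %in% onchr$gene_id, , drop = FALSE]
      inside <- ex$start <= p0 & p0 < ex$end
      for (j in which(inside)) {
        if (!ex$gene_id[j] %in% hits) { hits <- c(hits, ex$gene_id[j]); ev <- c(ev, ex$kind[j]) }
      }
    }
    if (length(hits) > 0) {
      rows[[length(rows) + 1]] <- data.frame(sentinel_id = sid, gene_id = hits,
                                             tier = "genic", evidence = ev,
                                             stringsAsFactors = FALSE)
      next
    }
    # tier 2: distal interaction intervals (0-based half-open)
    ia <- interactions$chrom == ch & interactions$start <= p0 & p0 < interactions$end
    if (any(ia)) {
      rows[[length(rows) + 1]] <- data.frame(
        sentinel_id = sid, gene_id = unique(interactions$gene_id[ia]),
        tier = "functional",
        evidence = interactions$source[ia][!duplicated(interactions$gene_id[ia])],
        stringsAsFactors = FALSE)
      next
    }
    # tier 3: all genes with TSS inside a TAD containing the sentinel
    sgr <- points_to_granges(ch, pos)
    tin <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(sgr, tads, ignore.strand = TRUE))
    if (length(tin) > 0 && nrow(onchr) > 0) {
      tss_gr <- points_to_granges(onchr$chrom, onchr$tss)
      gin <- GenomicRanges::findOverlaps(tss_gr, tads[tin], ignore.strand = TRUE)
      gid <- unique(onchr$gene_id[S4Vectors::queryHits(gin)])
      if (length(gid) > 0)
        rows[[length(rows) + 1]] <- data.frame(sentinel_id = sid, gene_id = gid,
                                               tier = "tad", evidence = "tad",
                                               stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sentinel_id = character(), gene_id = character(),
               tier = character(), evidence = character())
  class(out) <- c("target_assignment", "data.frame")
  out
}

#' Size-factor-normalised log counts per million
#'
#' log2(count / effective library size x 1e6 + 0.5), with effective library
#' sizes rescaled by median-of-ratios size factors (geometric-mean reference,
#' computed over genes expressed in every sample).
#'
#' @param counts gene x sample count matrix.
#' @return matrix of logCPM values.
#' @export
logcpm <- function(counts) {
  lib <- colSums(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) >= 10) {
    lg <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- exp(apply(lg - ref, 2, median))
    sf <- sf / exp(mean(log(sf)))
    lib <- lib * sf
  }
  log2(t(t(counts) / lib) * 1e6 + 0.5)
}

#' Fit a linear model with a single random intercept by profile REML
#'
#' The variance ratio lambda = sigma_u^2 / sigma_e^2 is profiled over a
#' bounded one-dimensional search with closed-form generalised least squares
#' at each lambda (block-diagonal Woodbury inverse per grouping level);
#' lambda = 0 (plain OLS) is always evaluated and kept if it maximises the
#' REML criterion. Wald inference uses a t reference with n - p degrees of
#' freedom.
#'
#' @param y response vector.
#' @param X design matrix (with intercept).
#' @param group factor of grouping labels (participant ids).
#' @param lambda_max upper bound of the variance-ratio search (default 1e4).
#' @return list: beta, se, p (per column of X), sigma2_u, sigma2_e, lambda,
#'   reml (criterion at optimum), converged.
#' @export
fit_random_intercept <- function(y, X, group, lambda_max = 1e4) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  g <- as.integer(factor(group))
  glev <- split(seq_len(n), g)
  crit <- .reml_closure(y, X, glev, n, p)
  f0 <- crit(0)
  opt <- optimise(function(lt) -crit(exp(lt))$reml, interval = c(-12, log(lambda_max)))
  fo <- crit(exp(opt$minimum))
  use0 <- f0$reml >= fo$reml
  lambda <- if (use0) 0 else exp(opt$minimum)
  fit <- if (use0) f0 else fo
  covb <- chol2inv(fit$XtViX_chol) * fit$sigma2
  se <- sqrt(diag(covb))
  beta <- drop(fit$beta)
  tval <- beta / se
  pv <- 2 * pt(-abs(tval), n - p)
  list(beta = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
       p = setNames(pv, colnames(X)),
       sigma2_u = lambda * fit$sigma2, sigma2_e = fit$sigma2,
       lambda = lambda, reml = fit$reml, converged = TRUE)
}

.reml_closure <- function(y, X, glev, n, p) {
  function(lambda) {
    # V = I + lambda Z Z' ; per group V_g^{-1} = I - lambda/(1+lambda n_g) J
    XtViX <- matrix(0, p, p); XtViy <- numeric(p)
    yViy <- 0; logdetV <- 0
    for (idx in glev) {
      ng <- length(idx)
      a <- lambda / (1 + lambda * ng)
      Xg <- X[idx, , drop = FALSE]; yg <- y[idx]
      sx <- colSums(Xg); sy <- sum(yg)
      XtViX <- XtViX + crossprod(Xg) - a * tcrossprod(sx)
      XtViy <- XtViy + crossprod(Xg, yg) - a * sx * sy
      yViy <- yViy + sum(yg^2) - a * sy^2
      logdetV <- logdetV + log1p(lambda * ng)
    }
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(list(reml = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
    rss <- yViy - sum(XtViy * beta)
    rss <- max(rss, 1e-12)
    sigma2 <- rss / (n - p)
    reml <- -0.5 * ((n - p) * log(sigma2) + logdetV + 2 * sum(log(diag(ch))))
    list(reml = reml, beta = beta, sigma2 = sigma2, XtViX_chol = ch)
  }
}

#' Restricted-likelihood criterion at a fixed variance ratio
#'
#' The profiled REML criterion that [fit_random_intercept()] maximises,
#' evaluated at a given lambda = sigma_u^2 / sigma_e^2; exposed so the
#' optimality of the returned ratio can be audited against a grid.
#'
#' @param y,X,group as [fit_random_intercept()].
#' @param lambda variance ratio (>= 0).
#' @return the REML criterion value (larger is better).
#' @export
reml_criterion <- function(y, X, group, lambda) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  glev <- split(seq_len(n), as.integer(factor(group)))
  .reml_closure(y, X, glev, n, p)(lambda)$reml
}

#' Methylation-expression association with participant random intercepts
#'
#' For each sentinel-gene pair: logCPM expression is regressed on the
#' sentinel's beta value plus covariates over the combined-depot samples,
#' with a per-participant random intercept absorbing the paired-depot
#' relatedness. BH q-values are computed across the tested pairs and the
#' significance gate is q < `q_thresh`.
#'
#' @param m `meth_matrix` covering the expression samples (betas looked up by
#'   participant + depot of each expression sample across all supplied
#'   matrices).
#' @param e `expr_matrix`.
#' @param pairs `target_assignment` (or any data.frame with sentinel_id,
#'   gene_id).
#' @param covars optional covariate matrix aligned to expression samples.
#' @param q_thresh FDR gate (default 0.01).
#' @param min_n minimum complete observations per pair (default 10).
#' @return data.frame of class `meth_expr_assoc`: sentinel_id, gene_id,
#'   slope, se, p, q, sigma2_u, sigma2_e, n, significant.
#' @export
meth_expr_assoc <- function(m, e, pairs, covars = NULL, q_thresh = 0.01,
                            min_n = 10) {
  le <- logcpm(e$counts)
  sheet <- e$sample_sheet
  if (is.list(m) && !inherits(m, "meth_matrix")) {
    # named list of meth matrices; look betas up by sample id across them
    beta_for <- function(site, sample_ids) {
      v <- rep(NA_real_, length(sample_ids))
      for (mm in m) {
        hit <- match(sample_ids, colnames(mm$betas))
        ok <- !is.na(hit) & site %in% rownames(mm$betas)
        if (any(ok)) v[ok] <- mm$betas[site, hit[ok]]
      }
      v
    }
  } else {
    beta_for <- function(site, sample_ids)
      m$betas[site, match(sample_ids, colnames(m$betas))]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    site <- pairs$sentinel_id[i]; gene <- pairs$gene_id[i]
    if (!gene %in% rownames(le)) return(NULL)
    meth <- beta_for(site, sheet$sample_id)
    yy <- le[gene, ]
    ok <- !is.na(meth) & !is.na(yy)
    if (!is.null(covars)) ok <- ok & !apply(is.na(as.matrix(covars)), 1, any)
    if (sum(ok) < min_n)
      return(data.frame(sentinel_id = site, gene_id = gene, slope = NA_real_,
                        se = NA_real_, p = NA_real_, sigma2_u = NA_real_,
                        sigma2_e = NA_real_, n = sum(ok), flagged = "too_few_obs",
                        stringsAsFactors = FALSE))
    X <- cbind(`(Intercept)` = 1, meth = meth[ok])
    if (!is.null(covars)) X <- cbind(X, as.matrix(covars)[ok, , drop = FALSE])
    fit <- fit_random_intercept(yy[ok], X, sheet$participant_id[ok])
    data.frame(sentinel_id = site, gene_id = gene,
               slope = fit$beta[["meth"]], se = fit$se[["meth"]],
               p = fit$p[["meth"]], sigma2_u = fit$sigma2_u,
               sigma2_e = fit$sigma2_e, n = sum(ok), flagged = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out$significant <- !is.na(out$q) & out$q < q_thresh
  class(out) <- c("meth_expr_assoc", "data.frame")
  out
}

#' Naive per-gene differential-expression fit (plumbing)
#'
#' OLS of logCPM on group plus covariates per gene, BH-adjusted. A deliberate
#' log-scale simplification standing in for a count-model fit; used only to
#' provide q-values for [de_enrichment()].
#'
#' @param e `expr_matrix`; `group` 0/1 vector; `covars` optional.
#' @param group case/control indicator aligned to expression samples.
#' @param covars optional covariate matrix.
#' @return data.frame: gene_id, effect, p, q.
#' @export
de_fit_naive <- function(e, group, covars = NULL) {
  le <- logcpm(e$counts)
  X <- .design(group, covars, ncol(le))
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- le %*% X %*% XtXinv
  res <- le - B %*% t(X)
  df <- ncol(le) - ncol(X)
  s2 <- rowSums(res^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])
  tv <- B[, 2] / se
  p <- pmin(pmax(2 * pt(-abs(tv), df), .Machine$double.xmin), 1)
  data.frame(gene_id = rownames(le), effect = B[, 2], p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE)
}

#' Differential-expression enrichment of target genes
#'
#' One-sided exact binomial comparing the observed number of differentially
#' expressed target genes with the background DE rate of the universe.
#'
#' @param target_genes character vector of target gene ids.
#' @param de_table data.frame with gene_id, q (from a DE fit).
#' @param q_thresh DE call threshold (default 0.01).
#' @param background_rate optional fixed background rate; default = DE rate
#'   over all genes in `de_table`.
#' @return list: k, n, observed_rate, background_rate, p (upper tail).
#' @export
de_enrichment <- function(target_genes, de_table, q_thresh = 0.01,
                          background_rate = NULL) {
  target_genes <- unique(target_genes)
  idx <- match(target_genes, de_table$gene_id)
  if (all(is.na(idx)) || length(target_genes) == 0) stop("no target genes in DE table")
  de <- de_table$q < q_thresh
  k <- sum(de[idx], na.rm = TRUE)
  n <- sum(!is.na(idx))
  p0 <- if (is.null(background_rate)) mean(de, na.rm = TRUE) else background_rate
  pv <- if (p0 >= 1) 1 else if (p0 <= 0) as.numeric(k > 0) * 0 + as.numeric(k == 0)
  else exact_binomial(k, n, p0, sided = "one")$p
  list(k = k, n = n, observed_rate = k / n, background_rate = p0, p = pv)
}
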