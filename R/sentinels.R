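# Locus clumping, sentinel selection, DMR extension and exact binomial sign
# tests (log-space, so tail probabilities below double underflow stay exact).

#' Clump significant sites into genomic loci and pick sentinels
#'
#' Default semantics are single-linkage chaining: sites on the same chromosome
#' at most `gap` bp apart are joined transitively, so a chain's ends may be
#' further than `gap` apart. `method = "window"` instead iteratively seeds a
#' locus at the lowest-p remaining site and claims everything within
#' +/-`gap` bp of it. The sentinel of a locus is its minimum-p site, ties
#' broken by lower genomic position.
#'
#' @param sig_sites data.frame with site_id, chrom, pos, p (and optionally
#'   effect) — typically a significant subset of a `meta_result` joined to
#'   site coordinates.
#' @param gap distance threshold in bp (default 5000).
#' @param method "chain" (default) or "window".
#' @return data.frame of class `sentinel_loci`: sentinel_id, chrom, pos,
#'   p, effect, n_members, span_bp, members (list column).
#' @export
clump_loci <- function(sig_sites, gap = 5000L, method = c("chain", "window")) {
  method <- match.arg(method)
  stopifnot(all(c("site_id", "chrom", "pos", "p") %in% names(sig_sites)))
  if (nrow(sig_sites) == 0) {
    out <- data.frame(sentinel_id = character(), chrom = character(),
                      pos = integer(), p = numeric(), effect = numeric(),
                      n_members = integer(), span_bp = integer())
    out$members <- list()
    class(out) <- c("sentinel_loci", "data.frame")
    return(out)
  }
  s <- sig_sites[order(sig_sites$chrom, sig_sites$pos), , drop = FALSE]
  if (!"effect" %in% names(s)) s$effect <- NA_real_
  loci <- list()
  for (ch in unique(s$chrom)) {
    d <- s[s$chrom == ch, , drop = FALSE]
    if (method == "chain") {
      brk <- c(TRUE, diff(d$pos) > gap)
      grp <- cumsum(brk)
    } else {
      grp <- rep(NA_integer_, nrow(d))
      g <- 0L
      remaining <- rep(TRUE, nrow(d))
      while (any(remaining)) {
        g <- g + 1L
        seed <- which(remaining)[order(d$p[remaining], d$pos[remaining])][1]
        claim <- remaining & abs(d$pos - d$pos[seed]) <= gap
        grp[claim] <- g
        remaining <- remaining & !claim
      }
    }
    for (gg in unique(grp)) {
      mem <- d[grp == gg, , drop = FALSE]
      sidx <- order(mem$p, mem$pos)[1]
      loci[[length(loci) + 1]] <- data.frame(
        sentinel_id = mem$site_id[sidx], chrom = ch, pos = mem$pos[sidx],
        p = mem$p[sidx], effect = mem$effect[sidx],
        n_members = nrow(mem), span_bp = max(mem$pos) - min(mem$pos),
        stringsAsFactors = FALSE)
      loci[[length(loci)]]$members <- list(mem$site_id)
    }
  }
  out <- do.call(rbind, loci)
  class(out) <- c("sentinel_loci", "data.frame")
  out
}

#' Extend a sentinel to a differentially methylated region
#'
#' Counts array sites within +/-`window` bp of the sentinel (the sentinel
#' itself excluded) whose direction of effect matches the sentinel and whose
#' Bonferroni-adjusted p is below `alpha`. The region is flagged as a DMR when
#' at least `n_flank` such sites exist. The Bonferroni denominator defaults to
#' the number of array sites inside the tested window(s); pass `bonf_n` to
#' use a study-wide denominator instead.
#'
#' @param sentinel one row of a `sentinel_loci` table (or a list with
#'   sentinel_id, chrom, pos, effect).
#' @param all_sites data.frame over all array sites: site_id, chrom, pos,
#'   effect, p (meta-analysis scale).
#' @param n_flank minimum consistent flanking sites (default 5).
#' @param window half-width in bp (default 5000).
#' @param alpha significance level after Bonferroni adjustment (default 0.05).
#' @param bonf_n Bonferroni denominator; default = sites in the window.
#' @return list: sentinel_id, n_consistent, is_dmr, width_bp, member_ids.
#' @export
extend_dmr <- function(sentinel, all_sites, n_flank = 5L, window = 5000L,
                       alpha = 0.05, bonf_n = NULL) {
  sid <- sentinel$sentinel_id
  row <- all_sites[all_sites$site_id == sid, , drop = FALSE]
  if (nrow(row) == 0) stop("sentinel ", sid, " absent from site table")
  inwin <- all_sites$chrom == row$chrom &
    abs(all_sites$pos - row$pos) <= window & all_sites$site_id != sid
  cand <- all_sites[inwin, , drop = FALSE]
  denom <- if (is.null(bonf_n)) nrow(cand) else bonf_n
  ok <- sign(cand$effect) == sign(row$effect) &
    pmin(cand$p * max(denom, 1), 1) < alpha
  qual <- cand[ok, , drop = FALSE]
  n_cons <- nrow(qual)
  memb <- c(sid, qual$site_id)
  width <- if (n_cons > 0) max(c(row$pos, qual$pos)) - min(c(row$pos, qual$pos)) else 0L
  list(sentinel_id = sid, n_consistent = n_cons, is_dmr = n_cons >= n_flank,
       width_bp = as.integer(width), member_ids = memb)
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact binomial test computed in log space
#'
#' Tail sums are accumulated as log-probabilities, so p-values far below
#' double-precision underflow (e.g. 1e-1000) are returned exactly on the log
#' scale. One-sided is the upper tail P(X >= k); two-sided doubles the smaller
#' tail (including the observed value) and caps at 1 — at p0 = 0.5 this equals
#' the minimum-likelihood two-sided test by symmetry.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @param p0 null success probability in (0,1).
#' @param sided "one" (upper tail) or "two".
#' @return list: `p` (double; 0 if underflowed), `log_p` (natural log, exact),
#'   `log10_p`, plus the inputs.
#' @export
exact_binomial <- function(k, n, p0 = 0.5, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (n <= 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  logpmf <- function(x) lchoose(n, x) + x * log(p0) + (n - x) * log1p(-p0)
  upper <- .logsumexp(logpmf(k:n))
  if (sided == "one") {
    lp <- upper
  } else {
    lower <- .logsumexp(logpmf(0:k))
    lp <- min(log(2) + min(upper, lower), 0)
  }
  lp <- min(lp, 0)
  list(p = exp(lp), log_p = lp, log10_p = lp / log(10),
       k = k, n = n, p0 = p0, sided = sided)
}

#' Cross-depot concordance of sentinel effects
#'
#' Tests whether sentinels discovered in one depot keep their direction of
#' effect in the other. A sentinel is "consistent" if its effect sign matches
#' in depot B, and "consistent and significant" if additionally its depot-B
#' p-value clears Bonferroni correction for the number of sentinels tested.
#' Direction consistency is tested with a two-sided exact binomial against
#' 0.5.
#'
#' @param sentinels_a `sentinel_loci` discovered in depot A (needs
#'   sentinel_id, effect).
#' @param results_b `meta_result` (or `assoc_result`) for depot B.
#' @param alpha significance level for the Bonferroni-corrected gate.
#' @return list: n_consistent, n_consistent_significant, n_total, binom
#'   (the [exact_binomial()] result on consistency).
#' @export
depot_concordance <- function(sentinels_a, results_b, alpha = 0.05) {
  ib <- match(sentinels_a$sentinel_id, results_b$site_id)
  missing <- is.na(ib)
  if (any(missing))
    message(sum(missing), " sentinels absent from depot B results; dropped")
  sa <- sentinels_a[!missing, , drop = FALSE]
  ib <- ib[!missing]
  n <- nrow(sa)
  consistent <- sign(sa$effect) == sign(results_b$effect[ib])
  signif_b <- results_b$p[ib] < alpha / max(n, 1)
  k <- sum(consistent)
  list(n_consistent = k,
       n_consistent_significant = sum(consistent & signif_b),
       n_total = n,
       binom = exact_binomial(k, n, 0.5, sided = "two"))
}
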