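# Transcription-factor / methylation interplay: TF-sentinel correlation, the
# mediation contrast (TF-target association with vs without adjustment for
# sentinel methylation) and CG positional density around motif occurrences.

#' Pearson correlation of TF expression with sentinel methylation
#'
#' @param tf_expr numeric vector (log-scale TF expression).
#' @param sentinel_meth numeric vector of beta values, aligned samples.
#' @return list: r, p, n.
#' @export
tf_sentinel_correlation <- function(tf_expr, sentinel_meth) {
  ok <- !is.na(tf_expr) & !is.na(sentinel_meth)
  if (sum(ok) < 10) stop("need >= 10 complete pairs")
  if (sd(tf_expr[ok]) == 0 || sd(sentinel_meth[ok]) == 0)
    stop("zero variance in one of the vectors")
  ct <- cor.test(tf_expr[ok], sentinel_meth[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Mediation contrast: TF-target association with and without methylation
#'
#' Fits target ~ TF (+ covariates, participant random intercept) and
#' target ~ TF + sentinel methylation (+ covariates, random intercept) on the
#' identical sample subset, and reports both TF coefficients, their
#' difference `delta`, and `delta / beta_unadjusted` (flagged undefined when
#' the unadjusted coefficient is below 1e-6 in magnitude). When methylation
#' is essentially collinear with TF expression (r2 > 0.99) the adjusted fit
#' is skipped and flagged.
#'
#' @param tf_expr,target_expr,sentinel_meth aligned numeric vectors.
#' @param covars optional covariate matrix.
#' @param participant grouping labels for the random intercept.
#' @return list of class `mediation_result`: beta_unadjusted, se_unadjusted,
#'   beta_adjusted, se_adjusted, delta, proportion_change, n, flagged.
#' @export
mediation_contrast <- function(tf_expr, target_expr, sentinel_meth,
                               covars = NULL, participant) {
  ok <- !is.na(tf_expr) & !is.na(target_expr) & !is.na(sentinel_meth) &
    !is.na(participant)
  if (!is.null(covars)) ok <- ok & !apply(is.na(as.matrix(covars)), 1, any)
  tf <- tf_expr[ok]; y <- target_expr[ok]; mm <- sentinel_meth[ok]
  pid <- participant[ok]
  C <- if (!is.null(covars)) as.matrix(covars)[ok, , drop = FALSE] else NULL
  X1 <- cbind(`(Intercept)` = 1, tf = tf)
  if (!is.null(C)) X1 <- cbind(X1, C)
  f1 <- fit_random_intercept(y, X1, pid)
  r2_tm <- suppressWarnings(cor(tf, mm))^2
  if (!is.na(r2_tm) && r2_tm > 0.99) {
    out <- list(beta_unadjusted = f1$beta[["tf"]], se_unadjusted = f1$se[["tf"]],
                beta_adjusted = NA_real_, se_adjusted = NA_real_,
                delta = NA_real_, proportion_change = NA_real_,
                n = sum(ok), flagged = "meth_collinear_with_tf")
    class(out) <- "mediation_result"
    return(out)
  }
  X2 <- cbind(X1[, 1:2, drop = FALSE], meth = mm)
  if (!is.null(C)) X2 <- cbind(X2, C)
  f2 <- fit_random_intercept(y, X2, pid)
  delta <- f1$beta[["tf"]] - f2$beta[["tf"]]
  prop <- if (abs(f1$beta[["tf"]]) < 1e-6) NA_real_ else delta / f1$beta[["tf"]]
  out <- list(beta_unadjusted = f1$beta[["tf"]], se_unadjusted = f1$se[["tf"]],
              beta_adjusted = f2$beta[["tf"]], se_adjusted = f2$se[["tf"]],
              delta = delta, proportion_change = prop, n = sum(ok),
              flagged = if (is.na(prop)) "unadjusted_near_zero" else "")
  class(out) <- "mediation_result"
  out
}

#' Positional CG density around motif occurrences
#'
#' Counts CG positions at each offset in [-flank, +flank] relative to motif
#' centres; minus-strand occurrences have their offsets mirrored so profiles
#' are in motif orientation. The total count equals the number of
#' (occurrence, CG) pairs within range.
#'
#' @param motifs GRanges of motif occurrences (strand used for flipping).
#' @param cg_chrom,cg_pos CG coordinates (1-based cytosine positions).
#' @param flank half-width of the profile (default 150).
#' @return integer vector of length 2*flank+1, names = offsets.
#' @export
motif_cg_profile <- function(motifs, cg_chrom, cg_pos, flank = 150L) {
  offsets <- (-flank):flank
  counts <- setNames(integer(length(offsets)), offsets)
  if (length(cg_pos) == 0 || length(motifs) == 0) return(counts)
  centre <- as.integer((GenomicRanges::start(motifs) + GenomicRanges::end(motifs)) %/% 2)
  mchr <- as.character(GenomicRanges::seqnames(motifs))
  mstr <- as.character(GenomicRanges::strand(motifs))
  for (i in seq_along(motifs)) {
    onchr <- which(cg_chrom == mchr[i])
    if (length(onchr) == 0) next
    off <- cg_pos[onchr] - centre[i]
    if (mstr[i] == "-") off <- -off
    off <- off[abs(off) <= flank]
    if (length(off) > 0) {
      tab <- table(off)
      counts[as.character(names(tab))] <- counts[as.character(names(tab))] +
        as.integer(tab)
    }
  }
  counts
}
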