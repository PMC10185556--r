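# Shared fixture builders (everything generated in code; no stored data).

make_sheet <- function(ids, group = NULL, participant = NULL, depot = "subq",
                       cohort = "discovery") {
  n <- length(ids)
  data.frame(sample_id = ids,
             cohort = cohort, depot = depot,
             participant_id = if (is.null(participant)) ids else participant,
             group = if (is.null(group)) rep(0L, n) else group,
             age = rep(50, n), sex = rep(0L, n), ethnicity = rep(0L, n),
             stringsAsFactors = FALSE)
}

make_meth <- function(betas, chrom = NULL, pos = NULL) {
  if (is.null(rownames(betas))) rownames(betas) <- paste0("cg", seq_len(nrow(betas)))
  if (is.null(colnames(betas))) colnames(betas) <- paste0("S", seq_len(ncol(betas)))
  if (is.null(chrom)) chrom <- rep("chr1", nrow(betas))
  if (is.null(pos)) pos <- seq(100L, by = 100000L, length.out = nrow(betas))
  meth_matrix(betas, chrom, pos, make_sheet(colnames(betas)))
}

# independent single-linkage chaining oracle: transitive closure of the
# pairwise <= gap relation, computed by repeated sweeps
chain_oracle <- function(chrom, pos, gap = 5000) {
  n <- length(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= gap &&
          grp[j] != grp[i]) {
        g <- min(grp[i], grp[j]); grp[grp == grp[i] | grp == grp[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}

# independent greedy LD-clump oracle on an explicit r2 matrix
clump_oracle <- function(p, r2mat, r2_max) {
  ord <- order(p)
  kept <- integer(0)
  for (i in ord) {
    if (all(r2mat[i, kept] < r2_max) || length(kept) == 0) kept <- c(kept, i)
  }
  sort(kept)
}
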