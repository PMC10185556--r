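# Matched-background permutation enrichment: sliding tolerance ladder for
# per-sentinel background sets, then feature / GWAS-state / pathway
# enrichment against 1000 matched replicates.

# run code with a locally seeded RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Per-site methylation mean/sd pool for permutation matching
#' @param m `meth_matrix` of the depot in which sentinels were discovered.
#' @return data.frame: site_id, chrom, pos, mean, sd.
#' @export
site_pool_stats <- function(m) {
  data.frame(site_id = rownames(m$betas), chrom = m$chrom, pos = m$pos,
             mean = rowMeans(m$betas, na.rm = TRUE),
             sd = apply(m$betas, 1, sd, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Build a matched permutation set for one sentinel
#'
#' Walks a sliding tolerance ladder: at rung r the tolerances are
#' (0.025 r) on the methylation mean and (0.0025 r) on the sd. Candidates are
#' pool sites within both tolerances, more than `min_dist` bp from the
#' sentinel (any chromosome difference qualifies) and not the sentinel
#' itself. The first rung with strictly more than `n_perm` candidates is
#' accepted and exactly `n_perm` sites are sampled without replacement from a
#' per-sentinel seeded stream (seed XOR sentinel index), so regeneration is
#' exact.
#'
#' @param sentinel_id site id of the sentinel.
#' @param pool output of [site_pool_stats()].
#' @param seed global RNG seed.
#' @param sentinel_index integer index of this sentinel in its list (folded
#'   into the stream seed).
#' @param n_perm matched sites per set (default 1000).
#' @param min_dist exclusion radius around the sentinel in bp (default 5000).
#' @param max_rung ladder ceiling (default 40, i.e. the full beta range).
#' @return list of class `perm_set`: sentinel_id, ids (length `n_perm`),
#'   rung, tol_mean, tol_sd, pool_size.
#' @export
build_permutation_set <- function(sentinel_id, pool, seed, sentinel_index = 1L,
                                  n_perm = 1000L, min_dist = 5000L,
                                  max_rung = 40L) {
  row <- pool[pool$site_id == sentinel_id, , drop = FALSE]
  if (nrow(row) != 1) stop("sentinel ", sentinel_id, " not in pool")
  far <- pool$chrom != row$chrom | abs(pool$pos - row$pos) > min_dist
  far <- far & pool$site_id != sentinel_id
  dmean <- abs(pool$mean - row$mean)
  dsd <- abs(pool$sd - row$sd)
  for (r in seq_len(max_rung)) {
    cand <- which(far & dmean <= 0.025 * r & dsd <= 0.0025 * r)
    if (length(cand) > n_perm) {
      ids <- .with_seed(bitwXor(as.integer(seed), as.integer(sentinel_index)),
                        sample(pool$site_id[cand], n_perm))
      return(structure(list(sentinel_id = sentinel_id, ids = ids, rung = r,
                            tol_mean = 0.025 * r, tol_sd = 0.0025 * r,
                            pool_size = length(cand)),
                       class = "perm_set"))
    }
  }
  stop(sprintf("no rung up to %d yields > %d matched sites for sentinel %s (pool %d)",
               max_rung, n_perm, sentinel_id, sum(far)))
}

#' Build permutation sets for a sentinel list
#' @param sentinel_ids character vector.
#' @param pool,seed,n_perm,min_dist,max_rung as [build_permutation_set()].
#' @return named list of `perm_set`.
#' @export
build_permutation_sets <- function(sentinel_ids, pool, seed, n_perm = 1000L,
                                   min_dist = 5000L, max_rung = 40L) {
  out <- lapply(seq_along(sentinel_ids), function(i)
    build_permutation_set(sentinel_ids[i], pool, seed, i, n_perm, min_dist, max_rung))
  names(out) <- sentinel_ids
  out
}

# site id -> logical: does its width-1 position overlap the feature track
.overlaps_feature <- function(site_ids, pool, features, label = NULL) {
  idx <- match(site_ids, pool$site_id)
  gr <- points_to_granges(pool$chrom[idx], pool$pos[idx], site_ids)
  f <- if (is.null(label)) features else features[features$label == label]
  # disjoint seqlevels (feature track absent from a chromosome) are expected
  suppressWarnings(GenomicRanges::countOverlaps(gr, f, ignore.strand = TRUE)) > 0
}

# shared enrichment machinery: observed count vs per-replicate background
.perm_enrichment <- function(obs_hits, bg_hit_matrix, label) {
  observed <- sum(obs_hits)
  bg_counts <- colSums(bg_hit_matrix)      # replicate j = j-th draw per sentinel
  expected <- mean(bg_counts)
  n_perm <- length(bg_counts)
  n_sent <- length(obs_hits)
  enriched <- observed >= expected && !(observed == 0 && expected == 0)
  emp <- if (enriched) (1 + sum(bg_counts >= observed)) / (n_perm + 1)
  else (1 + sum(bg_counts <= observed)) / (n_perm + 1)
  fold <- if (expected > 0) observed / expected else if (observed > 0) Inf else 0
  tab <- matrix(c(observed, n_sent - observed,
                  sum(bg_hit_matrix), length(bg_hit_matrix) - sum(bg_hit_matrix)),
                2, byrow = TRUE)
  fis <- fisher.test(tab)$p.value
  data.frame(label = label, observed = observed, expected = expected,
             fold = fold, fisher_p = fis, empirical_p = emp,
             direction = if (enriched) "enriched" else "depleted",
             stringsAsFactors = FALSE)
}

#' Feature enrichment of sentinels against matched permutation backgrounds
#'
#' For each feature label, compares the number of sentinels overlapping the
#' feature with the counts in each of the `n_perm` background replicates
#' (replicate j takes the j-th matched site of every sentinel). Reports fold
#' (observed over mean expected), a Fisher exact p on the pooled 2x2 table and
#' an empirical permutation p.
#'
#' @param sentinel_ids character vector of sentinel site ids.
#' @param permsets list from [build_permutation_sets()], aligned to sentinels.
#' @param features GRanges with a `label` column.
#' @param pool [site_pool_stats()] table carrying site coordinates.
#' @return data.frame of class `enrichment_result`, one row per label.
#' @export
feature_enrichment <- function(sentinel_ids, permsets, features, pool) {
  labels <- unique(features$label)
  rows <- lapply(labels, function(lab) {
    obs <- .overlaps_feature(sentinel_ids, pool, features, lab)
    bg <- vapply(permsets, function(ps) .overlaps_feature(ps$ids, pool, features, lab),
                 logical(length(permsets[[1]]$ids)))
    # bg: n_perm x n_sentinels; replicates are rows
    .perm_enrichment(obs, t(bg), lab)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' GWAS-signal overlap enrichment via shared chromatin-state intervals
#'
#' A sentinel "overlaps GWAS" iff the chromatin-state interval containing it
#' also contains a genome-wide-significant SNP (interval-level semantics; set
#' `label_level = TRUE` to count a match whenever sentinel and SNP fall in
#' intervals sharing a state label). Enrichment against the matched
#' backgrounds as in [feature_enrichment()].
#'
#' @param sentinel_ids,permsets,pool as [feature_enrichment()].
#' @param gwas_hits data.frame with chrom, pos of significant SNPs (already
#'   filtered, e.g. p < 5e-8).
#' @param states GRanges partitioning the covered genome, `label` column.
#' @param label_level match on state label instead of individual interval.
#' @return one-row `enrichment_result`.
#' @export
gwas_state_overlap <- function(sentinel_ids, permsets, pool, gwas_hits, states,
                               label_level = FALSE) {
  snp_gr <- points_to_granges(gwas_hits$chrom, gwas_hits$pos)
  snp_hit <- GenomicRanges::findOverlaps(snp_gr, states, ignore.strand = TRUE)
  hit_intervals <- unique(S4Vectors::subjectHits(snp_hit))
  n_outside <- nrow(gwas_hits) - length(unique(S4Vectors::queryHits(snp_hit)))
  if (n_outside > 0) message(n_outside, " significant SNPs outside any state interval")
  hit_labels <- unique(states$label[hit_intervals])
  site_flag <- function(ids) {
    idx <- match(ids, pool$site_id)
    gr <- points_to_granges(pool$chrom[idx], pool$pos[idx])
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, states, ignore.strand = TRUE))
    flag <- logical(length(ids))
    if (label_level) {
      flag[S4Vectors::queryHits(ov)] <-
        states$label[S4Vectors::subjectHits(ov)] %in% hit_labels
    } else {
      flag[S4Vectors::queryHits(ov)] <-
        S4Vectors::subjectHits(ov) %in% hit_intervals
    }
    flag
  }
  obs <- site_flag(sentinel_ids)
  bg <- vapply(permsets, function(ps) site_flag(ps$ids),
               logical(length(permsets[[1]]$ids)))
  out <- .perm_enrichment(obs, t(bg), "gwas_state")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Nearest gene with feature-class priority
#'
#' Overlaps are ranked promoter > 5'/3' UTR > exon > intron; among equal-rank
#' overlaps the gene with the nearest TSS wins, ties broken by lower TSS
#' coordinate. Sites overlapping nothing are intergenic and assigned the gene
#' with the nearest TSS on the site's chromosome.
#'
#' @param chrom,pos site coordinate (1-based).
#' @param genes `gene_models`.
#' @return list: gene_id, feature_class, distance_to_tss.
#' @export
nearest_gene <- function(chrom, pos, genes) {
  g <- genes$gene
  if (nrow(g) == 0) stop("empty gene set")
  onchr <- g[g$chrom == chrom, , drop = FALSE]
  classes <- c(promoter = 1, utr5 = 2, utr3 = 2, exon = 3, intron = 4)
  best_rank <- Inf; best_gene <- NA_character_; best_dist <- Inf; best_class <- "intergenic"
  if (nrow(onchr) > 0) {
    for (i in seq_len(nrow(onchr))) {
      gid <- onchr$gene_id[i]
      tss <- onchr$tss[i]
      dist <- abs(pos - tss)
      ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
      # exon coordinates 0-based half-open; pos is 1-based
      p0 <- pos - 1L
      rank_here <- Inf; class_here <- NA_character_
      if (dist <= genes$promoter_halfwidth) { rank_here <- 1; class_here <- "promoter" }
      if (nrow(ex) > 0 && rank_here > 1) {
        inside <- ex$start <= p0 & p0 < ex$end
        if (any(inside)) {
          kinds <- ex$kind[inside]
          if (any(kinds %in% c("utr5", "utr3"))) { rank_here <- 2; class_here <- "utr" }
          else { rank_here <- 3; class_here <- "exon" }
        } else {
          body_lo <- min(ex$start); body_hi <- max(ex$end)
          if (body_lo <= p0 && p0 < body_hi && rank_here > 3) {
            rank_here <- 4; class_here <- "intron"
          }
        }
      }
      if (rank_here < best_rank ||
          (rank_here == best_rank && (dist < best_dist ||
                                      (dist == best_dist && !is.na(best_gene) &&
                                       tss < onchr$tss[match(best_gene, onchr$gene_id)])))) {
        best_rank <- rank_here; best_gene <- gid; best_dist <- dist
        if (!is.na(class_here)) best_class <- class_here
      }
    }
  }
  if (!is.finite(best_rank)) {   # intergenic: nearest TSS, tie -> lower coordinate
    cand <- if (nrow(onchr) > 0) onchr else g
    d <- abs(pos - cand$tss)
    pick <- order(d, cand$tss)[1]
    best_gene <- cand$gene_id[pick]; best_dist <- d[pick]; best_class <- "intergenic"
  }
  list(gene_id = best_gene, feature_class = best_class,
       distance_to_tss = as.integer(best_dist))
}

#' Pathway enrichment of sentinel nearest genes vs permutation gene lists
#'
#' Gene lists are deduplicated (one sentinel per gene, one permutation per
#' gene) before counting. For each gene set the observed unique-gene hit count
#' is compared with the hit counts of the permutation replicates.
#'
#' @param sentinel_genes character vector (nearest gene per sentinel).
#' @param permset_genes list of character vectors, replicate j = nearest genes
#'   of the j-th matched site of every sentinel.
#' @param genesets named list from [read_gmt()].
#' @param universe optional gene universe; sets with no universe genes are
#'   skipped with a message.
#' @return data.frame: set, observed, expected, fold, empirical_p.
#' @export
pathway_enrichment <- function(sentinel_genes, permset_genes, genesets,
                               universe = NULL) {
  obs_genes <- unique(sentinel_genes)
  perm_genes <- lapply(permset_genes, unique)
  rows <- lapply(names(genesets), function(nm) {
    gs <- genesets[[nm]]
    if (!is.null(universe)) {
      gs <- intersect(gs, universe)
      if (length(gs) == 0) { message("gene set ", nm, " empty in universe; skipped"); return(NULL) }
    }
    observed <- sum(obs_genes %in% gs)
    bg <- vapply(perm_genes, function(pg) sum(pg %in% gs), 0L)
    expected <- mean(bg)
    enriched <- observed >= expected && !(observed == 0 && expected == 0)
    emp <- if (enriched) (1 + sum(bg >= observed)) / (length(bg) + 1)
    else (1 + sum(bg <= observed)) / (length(bg) + 1)
    data.frame(set = nm, observed = observed, expected = expected,
               fold = if (expected > 0) observed / expected else if (observed > 0) Inf else 0,
               empirical_p = emp,
               direction = if (enriched) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
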