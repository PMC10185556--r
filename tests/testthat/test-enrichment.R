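make_pool <- function(n, mean = NULL, sd = NULL, chrom = "chr1",
                      spacing = 10000L) {
  data.frame(site_id = sprintf("p%04d", seq_len(n)), chrom = chrom,
             pos = seq(10000L, by = spacing, length.out = n),
             mean = if (is.null(mean)) runif(n) else mean,
             sd = if (is.null(sd)) runif(n, 0.01, 0.1) else sd)
}

test_that("the tolerance ladder stops at the first rung with enough matches", {
  set.seed(11)
  # rung 1 already sufficient: everything matches exactly
  pool <- make_pool(1500, mean = 0.5, sd = 0.05)
  ps <- build_permutation_set(pool$site_id[1], pool, seed = 1)
  expect_equal(ps$rung, 1)
  expect_equal(c(ps$tol_mean, ps$tol_sd), c(0.025, 0.0025))
  expect_length(unique(ps$ids), 1000)
  expect_false(pool$site_id[1] %in% ps$ids)

  # 500 candidates at rung 1, >1000 only at rung 2
  pool2 <- make_pool(2000, mean = c(0.5, rep(0.51, 500), rep(0.54, 1000),
                                    rep(0.9, 499)), sd = 0.05)
  ps2 <- build_permutation_set(pool2$site_id[1], pool2, seed = 1)
  expect_equal(ps2$rung, 2)
  expect_equal(ps2$tol_mean, 0.05)

  # all candidates within 5 kb -> error
  pool3 <- make_pool(1200, mean = 0.5, sd = 0.05, spacing = 2L)
  expect_error(build_permutation_set(pool3$site_id[1], pool3, seed = 1),
               "matched sites")

  # regeneration with the same seed is exact; different index differs
  ps_a <- build_permutation_set(pool$site_id[1], pool, seed = 9, sentinel_index = 3)
  ps_b <- build_permutation_set(pool$site_id[1], pool, seed = 9, sentinel_index = 3)
  ps_c <- build_permutation_set(pool$site_id[1], pool, seed = 9, sentinel_index = 4)
  expect_identical(ps_a$ids, ps_b$ids)
  expect_false(identical(ps_a$ids, ps_c$ids))
  # matched sites honour the accepted tolerances
  idx <- match(ps_a$ids, pool$site_id)
  expect_true(all(abs(pool$mean[idx] - pool$mean[1]) <= ps_a$tol_mean))
  expect_true(all(abs(pool$sd[idx] - pool$sd[1]) <= ps_a$tol_sd))
})

test_that("feature enrichment has exact degenerate behaviour and a brute-force match", {
  set.seed(12)
  pool <- make_pool(1500, mean = 0.5, sd = 0.05)
  sent <- pool$site_id[1:10]
  ps <- build_permutation_sets(sent, pool, seed = 2, n_perm = 200)

  # a feature covering every site: fold 1, empirical p 1
  cover <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e7), label = "all")
  fe <- feature_enrichment(sent, ps, cover, pool)
  expect_equal(fe$fold, 1)
  expect_equal(fe$empirical_p, 1)

  # a label overlapping nothing: observed 0, depletion side
  nohit <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10), label = "none")
  fe0 <- feature_enrichment(sent, ps, nohit, pool)
  expect_equal(fe0$observed, 0)
  expect_equal(fe0$fold, 0)
  expect_equal(fe0$direction, "depleted")

  # brute-force recount of the empirical p over all replicates
  some <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(pool$pos[seq(1, 900, 3)],
                                                  width = 2), label = "f")
  fe2 <- feature_enrichment(sent, ps, some, pool)
  inf <- function(ids) {
    idx <- match(ids, pool$site_id)
    GenomicRanges::countOverlaps(points_to_granges(pool$chrom[idx], pool$pos[idx]),
                                 some) > 0
  }
  obs <- sum(inf(sent))
  bg <- vapply(seq_len(200), function(j)
    sum(vapply(ps, function(p) inf(p$ids[j]), TRUE)), 0L)
  emp <- if (obs >= mean(bg)) (1 + sum(bg >= obs)) / 201 else (1 + sum(bg <= obs)) / 201
  expect_equal(fe2$observed, obs)
  expect_equal(fe2$expected, mean(bg))
  expect_equal(fe2$empirical_p, emp)
  expect_gte(fe2$empirical_p, 1 / 201)
})

test_that("GWAS-state overlap uses interval-level semantics by default", {
  pool <- make_pool(40, mean = 0.5, sd = 0.05, spacing = 1000L)
  # two intervals share the label "enh": SNP sits in the second only
  states <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(9500, 20500), width = 2000),
                                   label = c("enh", "enh"))
  gwas_hits <- data.frame(chrom = "chr1", pos = 21000L)
  sent <- pool$site_id[1]      # pos 10000, first interval
  ps <- list(structure(list(sentinel_id = sent, ids = pool$site_id[30:34]),
                       class = "perm_set"))
  res <- gwas_state_overlap(sent, ps, pool, gwas_hits, states)
  expect_equal(res$observed, 0)       # same label, different interval
  res_lab <- gwas_state_overlap(sent, ps, pool, gwas_hits, states,
                                label_level = TRUE)
  expect_equal(res_lab$observed, 1)

  sent2 <- pool$site_id[12]   # pos 21000, in the SNP's interval
  ps2 <- list(structure(list(sentinel_id = sent2, ids = pool$site_id[30:34]),
                        class = "perm_set"))
  expect_equal(gwas_state_overlap(sent2, ps2, pool, gwas_hits, states)$observed, 1)

  # no significant SNPs at all
  expect_equal(gwas_state_overlap(sent, ps, pool,
                                  data.frame(chrom = character(), pos = integer()),
                                  states)$observed, 0)
})

test_that("nearest-gene assignment follows the feature-class priority ranking", {
  gene <- data.frame(gene_id = c("A", "B"), chrom = "chr1", strand = "+",
                     tss = c(1000L, 52000L))
  exons <- data.frame(gene_id = c("A", "A", "B"),
                      start = c(999L, 20000L, 51999L),
                      end = c(1500L, 21000L, 52500L),
                      kind = c("exon", "exon", "exon"))
  gm <- gene_models(gene, exons, promoter_halfwidth = 5000L)

  # site in A's intron (between exons) but within B's promoter window
  hit <- nearest_gene("chr1", 10000L, gm)
  expect_equal(hit$feature_class, "intron")
  expect_equal(hit$gene_id, "A")
  hit2 <- nearest_gene("chr1", 49000L, gm)   # B promoter beats intergenic
  expect_equal(hit2$gene_id, "B")
  expect_equal(hit2$feature_class, "promoter")

  # promoter beats intron when both apply
  gm2 <- gene_models(gene, exons, promoter_halfwidth = 15000L)
  hit3 <- nearest_gene("chr1", 10000L, gm2)
  expect_equal(hit3$feature_class, "promoter")

  # intergenic equidistant between two TSS -> lower-coordinate gene
  mid <- nearest_gene("chr1", 26500L, gm)
  expect_equal(abs(26500 - 1000), abs(26500 - 52000))
  expect_equal(mid$gene_id, "A")
  expect_equal(mid$feature_class, "intergenic")

  expect_error(nearest_gene("chr1", 1,
                            gene_models(gene[0, ], exons[0, ])), "empty")
})

test_that("pathway enrichment deduplicates genes and recovers planted sets", {
  set.seed(13)
  universe <- sprintf("g%04d", 1:5000)
  in_set <- universe[1:50]
  sent_genes <- sample(in_set, 20)
  perm_genes <- lapply(1:500, function(j) sample(universe, 20))
  res <- pathway_enrichment(sent_genes, perm_genes,
                            list(planted = in_set, everything = universe),
                            universe = universe)
  expect_lte(res$empirical_p[res$set == "planted"], 0.002)
  expect_equal(res$fold[res$set == "everything"], 1)
  # duplicated sentinel genes are counted once
  dup <- pathway_enrichment(c(sent_genes, sent_genes[1:5]), perm_genes,
                            list(planted = in_set), universe = universe)
  expect_equal(dup$observed, res$observed[res$set == "planted"])
  expect_message(
    pathway_enrichment(sent_genes, perm_genes, list(empty = "not_in_universe"),
                       universe = universe), "skipped")
})
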