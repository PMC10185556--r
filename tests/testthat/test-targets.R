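test_that("TAD hierarchy merge removes exactly the strictly nested intervals", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 200, 400, 1500, 1500),
                                                c(1000, 400, 1000, 2500, 2500)),
                               label = "tad")
  m <- merge_tads(gr)
  # [200,400] and [400,1000] nested in [1,1000]; duplicates collapse to one
  expect_equal(length(m), 2)
  expect_equal(GenomicRanges::start(m), c(1, 1500))

  # partial overlap retained
  po <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 400), c(600, 1000)))
  expect_equal(length(merge_tads(po)), 2)

  # idempotence
  expect_equal(GenomicRanges::ranges(merge_tads(m)), GenomicRanges::ranges(m))
})

test_that("target assignment respects the three-tier hierarchy exclusively", {
  gene <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1", strand = "+",
                     tss = c(10000L, 200000L, 260000L))
  exons <- data.frame(gene_id = c("G1", "G2", "G3"),
                      start = c(9999L, 199999L, 259999L),
                      end = c(12000L, 202000L, 262000L), kind = "exon")
  gm <- gene_models(gene, exons)
  inter <- structure(data.frame(chrom = "chr1", start = 99000L, end = 101000L,
                                gene_id = "G2", source = "hic"),
                     class = c("interaction_map", "data.frame"))
  tads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 150001), c(150000, 400000)),
                                 label = "tad")
  sent <- data.frame(sentinel_id = c("in_exon", "in_distal", "in_tad_only"),
                     chrom = "chr1", pos = c(10500L, 100000L, 300000L))
  ta <- assign_targets(sent, gm, inter, tads)
  expect_equal(ta$tier[ta$sentinel_id == "in_exon"], "genic")
  expect_equal(ta$gene_id[ta$sentinel_id == "in_exon"], "G1")
  expect_equal(ta$tier[ta$sentinel_id == "in_distal"], "functional")
  expect_equal(ta$gene_id[ta$sentinel_id == "in_distal"], "G2")
  tadrows <- ta[ta$sentinel_id == "in_tad_only", ]
  expect_true(all(tadrows$tier == "tad"))
  expect_setequal(tadrows$gene_id, c("G2", "G3"))  # TSSs inside the second TAD

  # tier exclusivity across any sentinel
  tiers_per <- tapply(ta$tier, ta$sentinel_id, function(x) length(unique(x)))
  expect_true(all(tiers_per == 1))
})

test_that("the random-intercept fitter reduces to OLS and matches lme4", {
  set.seed(14)
  n_p <- 30
  pid <- rep(sprintf("P%02d", 1:n_p), each = 2)
  x <- runif(2 * n_p, 0.2, 0.8)
  # sigma_u = 0: agreement with plain OLS to 3 decimals (and much better)
  y0 <- 1 - 2 * x + rnorm(2 * n_p, 0, 0.3)
  f0 <- fit_random_intercept(y0, cbind(1, x = x), pid)
  ols <- lm(y0 ~ x)
  expect_equal(unname(f0$beta[2]), unname(coef(ols)[2]), tolerance = 1e-3)

  # with a real random intercept: matches lme4 REML closely
  u <- rnorm(n_p, 0, 0.5)
  y <- 1 - 2 * x + u[as.integer(factor(pid))] + rnorm(2 * n_p, 0, 0.3)
  f <- fit_random_intercept(y, cbind(1, x = x), pid)
  lmm <- lme4::lmer(y ~ x + (1 | pid), REML = TRUE)
  expect_equal(unname(f$beta[2]), unname(lme4::fixef(lmm)[2]), tolerance = 1e-4)
  expect_equal(unname(f$se[2]), sqrt(as.matrix(lme4::vcov.merMod(lmm))[2, 2]),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lmm))$vcov
  expect_equal(f$sigma2_u, vc[1], tolerance = 1e-3)
  expect_equal(f$sigma2_e, vc[2], tolerance = 1e-3)

  # profile optimality: the returned ratio beats a 21-point grid over [0,100]
  grid <- seq(0, 100, length.out = 21)
  gridml <- vapply(grid, function(l) reml_criterion(y, cbind(1, x = x), pid, l), 0)
  expect_gte(f$reml, max(gridml) - 1e-8)
})

test_that("shuffled participant labels collapse the intercept variance", {
  set.seed(15)
  n_p <- 40
  pid <- rep(sprintf("P%02d", 1:n_p), each = 2)
  x <- runif(2 * n_p, 0.2, 0.8)
  u <- rnorm(n_p, 0, 0.6)
  su_true <- su_shuf <- numeric(10)
  for (r in 1:10) {
    y <- 1 - 2 * x + u[as.integer(factor(pid))] + rnorm(2 * n_p, 0, 0.3)
    su_true[r] <- fit_random_intercept(y, cbind(1, x = x), pid)$sigma2_u
    su_shuf[r] <- fit_random_intercept(y, cbind(1, x = x), sample(pid))$sigma2_u
  }
  expect_lt(median(su_shuf), median(su_true))
})

test_that("methylation-expression slopes are recovered within 2 SE", {
  set.seed(16)
  hits <- 0L; n_rep <- 40
  for (r in seq_len(n_rep)) {
    n_p <- 40
    pid <- rep(sprintf("P%02d", 1:n_p), each = 2)
    meth <- runif(2 * n_p, 0.2, 0.8)
    u <- rnorm(n_p, 0, 0.5)
    y <- 3 - 2 * meth + u[as.integer(factor(pid))] + rnorm(2 * n_p, 0, 0.3)
    f <- fit_random_intercept(y, cbind(1, meth = meth), pid)
    if (abs(f$beta[["meth"]] - (-2)) <= 2 * f$se[["meth"]]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("null methylation-expression pairs give uniform p-values", {
  set.seed(17)
  pvals <- vapply(1:300, function(r) {
    n_p <- 25
    pid <- rep(sprintf("P%02d", 1:n_p), each = 2)
    meth <- runif(2 * n_p, 0.2, 0.8)
    y <- rnorm(2 * n_p) + rnorm(n_p, 0, 0.5)[as.integer(factor(pid))]
    fit_random_intercept(y, cbind(1, meth = meth), pid)$p[["meth"]]
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("meth_expr_assoc wires matrices, pairs and the gate together", {
  cfg <- sim_config(n_sites = 1200, n_genes = 150, n_snps = 10, seed = 61,
                    n_mqtl = 0, n_chains = 0, n_target_links = 25,
                    n_mediation = 0, n_ref = 20, target_slope = -3)
  sim <- suppressWarnings(simulate_cohort(cfg))
  pairs <- data.frame(sentinel_id = sim$truth$targets$site_id,
                      gene_id = sim$truth$targets$gene_id)
  ma <- meth_expr_assoc(list(sim$meth$repl_subq, sim$meth$repl_visc),
                        sim$expr, pairs)
  expect_equal(nrow(ma), nrow(sim$truth$targets))
  expect_gte(nrow(ma), 20)
  expect_true(all(ma$n == ncol(sim$expr$counts)))
  expect_gte(mean(abs(ma$slope - (-3)) < 2 * ma$se), 0.8)
  expect_true(all(ma$sigma2_u >= 0 & ma$sigma2_e >= 0))
})

test_that("differential-expression enrichment tails behave at the extremes", {
  de <- data.frame(gene_id = sprintf("g%03d", 1:500),
                   q = c(rep(0.001, 25), runif(475, 0.2, 1)))
  # all 50 targets DE at background rate 0.05 -> astronomically small p
  de2 <- data.frame(gene_id = sprintf("g%03d", 1:500),
                    q = c(rep(0.001, 50), runif(450, 0.2, 1)))
  r <- de_enrichment(sprintf("g%03d", 1:50), de2, background_rate = 0.05)
  expect_lt(r$p, 1e-40)
  # background rate 1 -> p = 1
  expect_equal(de_enrichment(sprintf("g%03d", 1:50), de,
                             background_rate = 1)$p, 1)
  # random targets: p has no systematic excess
  set.seed(18)
  ps <- vapply(1:50, function(i)
    de_enrichment(sample(de$gene_id, 30), de)$p, 0)
  expect_gt(mean(ps > 0.05), 0.6)
  expect_error(de_enrichment(character(0), de), "no target genes")
})
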