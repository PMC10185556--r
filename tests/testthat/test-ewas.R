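test_that("site filtering has set semantics and is idempotent", {
  b <- matrix(runif(20), 10, 2,
              dimnames = list(sprintf("cg%02d", 1:10), c("S1", "S2")))
  m <- make_meth(b)
  f1 <- suppressMessages(filter_sites(m, c("cg01", "cg05", "cg09")))
  expect_equal(nrow(f1$betas), 7)
  f2 <- suppressMessages(filter_sites(m, c("cg01", "not_there")))
  expect_equal(nrow(f2$betas), 9)
  f3 <- suppressMessages(filter_sites(f1, c("cg01", "cg05", "cg09")))
  expect_identical(f3$betas, f1$betas)
  expect_warning(filter_sites(m, character(0)), "empty")
})

test_that("quantile normalisation matches hand-computed order-statistic means", {
  b <- matrix(c(1, 2, 3, 4, 5, 6) / 10, ncol = 2)
  m <- make_meth(b)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$betas[, 1]), c(2.5, 3.5, 4.5) / 10)
  expect_equal(unname(qn$betas[, 2]), c(2.5, 3.5, 4.5) / 10)

  # identical samples are a fixed point
  b2 <- matrix(rep(runif(5), 2), ncol = 2)
  qn2 <- quantile_normalize(make_meth(b2))
  expect_equal(qn2$betas, make_meth(b2)$betas, tolerance = 1e-12)

  # a monotone transform of a sample normalises to the same values
  set.seed(4)
  x <- runif(50)
  b3 <- cbind(x, plogis(5 * (x - 0.5)), runif(50))
  qn3 <- quantile_normalize(make_meth(b3))
  expect_equal(unname(qn3$betas[, 1]), unname(qn3$betas[, 2]), tolerance = 1e-12)
})

test_that("quantile normalisation agrees with the limma reference on complete data", {
  set.seed(5)
  b <- matrix(runif(200), 50, 4)
  qn <- quantile_normalize(make_meth(b))
  ref <- limma::normalizeQuantiles(b)
  expect_equal(unname(qn$betas), unname(ref), tolerance = 1e-10)
})

test_that("control-probe PCs capture technical variance with the right count", {
  set.seed(6)
  score <- rnorm(20)
  rank1 <- outer(rnorm(30), score)
  pcs <- control_probe_pcs(rank1, 0.95)
  expect_equal(ncol(pcs), 1)
  expect_gt(attr(pcs, "explained")[1], 0.999)

  noise <- matrix(rnorm(30 * 20), 30, 20)
  pcs2 <- control_probe_pcs(noise, 0.95)
  expect_gt(ncol(pcs2), 10)   # white noise needs most components
  cors <- cor(pcs2)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
})

test_that("per-site association equals a brute-force normal-equations solve", {
  set.seed(7)
  n <- 20
  b <- matrix(runif(8 * n, 0.2, 0.8), 8, n)
  m <- make_meth(b)
  pheno <- rep(c(0, 1), each = n / 2)
  covars <- cbind(age = rnorm(n), pc = rnorm(n))
  res <- site_association(m, pheno, covars)
  X <- cbind(1, pheno, covars)
  for (i in 1:8) {
    beta_bf <- solve(t(X) %*% X, t(X) %*% b[i, ])
    expect_lt(abs(res$effect[i] - beta_bf[2]), 1e-10)
    r <- b[i, ] - X %*% beta_bf
    s2 <- sum(r^2) / (n - ncol(X))
    se_bf <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    expect_lt(abs(res$se[i] - se_bf), 1e-10)
  }
  # missing values: listwise deletion per site
  b[1, 1:3] <- NA
  m2 <- make_meth(b)
  res2 <- site_association(m2, pheno, covars)
  keep <- 4:n
  f <- summary(lm(b[1, keep] ~ X[keep, -1]))$coefficients
  expect_equal(res2$effect[1], f[2, 1], tolerance = 1e-10)
  expect_equal(res2$n[1], n - 3)

  expect_error(site_association(m, pheno, cbind(dup = pheno)), "collinearity")
})

test_that("null phenotypes give uniform association p-values", {
  set.seed(8)
  cfg <- sim_config(n_sites = 2000, n_genes = 10, n_snps = 4, frac_diff = 0,
                    n_mqtl = 0, n_chains = 0, n_target_links = 0,
                    n_mediation = 0, n_dmr_clusters = 0, n_ref = 20,
                    batch_sd = 0, seed = 88)
  sim <- suppressWarnings(simulate_cohort(cfg))
  m <- sim$meth$disc_subq
  res <- site_association(m, m$sample_sheet$group)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("IVW meta-analysis matches closed forms and halves self-variance", {
  a <- data.frame(site_id = c("s1", "s2"), effect = c(1, 1), se = c(1, 1),
                  p = 0.05, q = 0.05, n = 10, direction = 1, cohort = "a",
                  skipped = FALSE)
  b <- a; b$effect <- c(3, 1); b$se <- c(1, 2); b$cohort <- "b"
  mt <- ivw_meta(a, b)
  expect_equal(mt$effect[mt$site_id == "s1"], 2)
  expect_equal(mt$se[mt$site_id == "s1"], 1 / sqrt(2))
  expect_equal(mt$effect[mt$site_id == "s2"], 1)
  expect_equal(mt$se[mt$site_id == "s2"], sqrt(1 / 1.25), tolerance = 1e-12)
  expect_equal(mt$Q[mt$site_id == "s2"], 0)

  self <- ivw_meta(a, a)
  expect_equal(self$se, a$se / sqrt(2))
  expect_equal(self$effect, a$effect)
  expect_equal(self$I2, c(0, 0))
})

test_that("BH q-values match hand computation and are order-equivariant", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.5, 0.04, 0.2)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})

test_that("the replication gate enforces all three conditions and monotonicity", {
  mk <- function(eff, p, q) data.frame(site_id = "s1", effect = eff, se = 0.01,
                                       p = p, q = q, n = 96, direction = sign(eff),
                                       cohort = "x", skipped = FALSE)
  meta <- data.frame(site_id = "s1", effect = -0.05, se = 0.005, p = 5e-8,
                     q = 5e-8, Q = 0, I2 = 0)
  g <- replication_gate(mk(-0.05, 1e-4, 0.005), mk(-0.04, 1e-3, 0.005), meta)
  expect_equal(g$sites, "s1"); expect_equal(c(g$k, g$n), c(1, 1))

  g2 <- replication_gate(mk(-0.05, 1e-4, 0.005), mk(0.04, 1e-3, 0.005), meta)
  expect_length(g2$sites, 0)
  expect_equal(c(g2$k, g2$n), c(0, 1))   # still in the sign-test denominator

  # tightening any threshold never adds sites
  g3 <- replication_gate(mk(-0.05, 1e-4, 0.005), mk(-0.04, 1e-3, 0.005), meta,
                         q_thresh = 0.001)
  expect_true(all(g3$sites %in% g$sites))
  g4 <- replication_gate(mk(-0.05, 1e-4, 0.005), mk(-0.04, 1e-3, 0.005), meta,
                         p_meta = 1e-9)
  expect_true(all(g4$sites %in% g$sites))
})

test_that("sensitivity refits quantify attenuation under planted confounding", {
  set.seed(9)
  n <- 80
  conf <- rnorm(n)
  pheno <- as.numeric(runif(n) < plogis(2 * conf))
  b <- matrix(0.5 + 0.08 * conf + rnorm(5 * n, 0, 0.02), 5, n, byrow = TRUE)
  b <- pmin(pmax(b, 0), 1)
  m <- make_meth(b)
  sr <- sensitivity_refit(m, pheno, covars = NULL, extra = cbind(conf = conf))
  expect_gt(median(sr$attenuation), 0.8)   # confounder explains the signal

  noise <- cbind(z = rnorm(n))
  sr2 <- sensitivity_refit(m, pheno, covars = NULL, extra = noise)
  expect_lt(abs(median(sr2$attenuation)), 0.2)

  expect_error(sensitivity_refit(m, pheno, covars = cbind(x = conf),
                                 extra = cbind(x2 = conf)), "collinearity")
})
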