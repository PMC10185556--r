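make_geno <- function(dos, chrom = NULL, pos = NULL, ea = NULL, oa = NULL) {
  n <- nrow(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("rs%02d", seq_len(n))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("P%03d", seq_len(ncol(dos)))
  geno_matrix(dos, chrom %||% rep("chr1", n),
              pos %||% seq(1e5, by = 1e4, length.out = n),
              ea %||% rep("A", n), oa %||% rep("G", n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the cis-mQTL scan recovers planted slopes and applies the filters", {
  set.seed(20)
  n <- 500
  d <- matrix(rbinom(3 * n, 2, 0.3), 3, n,
              dimnames = list(sprintf("rs%02d", 1:3), sprintf("P%03d", 1:n)))
  g <- make_geno(d, pos = c(1e5, 1e5 + 500001, 2e5),
                 ea = c("A", "A", "A"), oa = c("G", "G", "T"))
  # SNP3 is A/T palindromic; give it MAF ~0.45
  g$dosages[3, ] <- rbinom(n, 2, 0.45)
  g$maf[3] <- min(mean(g$dosages[3, ]) / 2, 1 - mean(g$dosages[3, ]) / 2)
  y <- 0.4 + 0.05 * d[1, ] + rnorm(n, 0, 0.05)
  b <- matrix(pmin(pmax(y, 0), 1), 1, n, dimnames = list("cgA", colnames(d)))
  m <- meth_matrix(b, "chr1", 1e5, make_sheet(colnames(d), participant = colnames(d)))
  rec <- mqtl_scan(g, m, "cgA")
  # window edge: SNP at distance 500,001 excluded; palindromic MAF>0.42 excluded
  expect_equal(rec$snp_id, "rs01")
  expect_lt(abs(rec$beta - 0.05), 2 * rec$se)
  expect_equal(rec$n, n)
  expect_true(rec$r2 > 0 && rec$r2 < 1)

  # empty window
  m2 <- meth_matrix(b, "chr9", 1e5, make_sheet(colnames(d), participant = colnames(d)))
  expect_message(r0 <- mqtl_scan(g, m2, "cgA"), "no in-window")
  expect_equal(nrow(r0), 0)
})

test_that("greedy LD clumping matches an independent oracle on small fixtures", {
  set.seed(21)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  for (rep in 1:10) {
    k <- sample(4:8, 1)
    dos <- matrix(0, k, n, dimnames = list(sprintf("rs%02d", 1:k),
                                           sprintf("P%03d", 1:n)))
    for (i in 1:k) {
      # correlate some SNPs with the base, others independent
      dos[i, ] <- if (runif(1) < 0.5)
        ifelse(runif(n) < 0.9, base, rbinom(n, 2, 0.4)) else rbinom(n, 2, 0.4)
    }
    g <- make_geno(dos)
    rec <- data.frame(snp_id = rownames(dos), site_id = "s", beta = 0.05,
                      se = 0.01, p = runif(k, 1e-10, 1e-3), r2 = 0.1,
                      distance = 0, effect_allele = "A", other_allele = "G",
                      maf = 0.4, n = n)
    got <- ld_clump(rec, g, r2_max = 0.05)
    r2mat <- cor(t(dos))^2; diag(r2mat) <- 0
    want <- clump_oracle(rec$p, r2mat, 0.05)
    expect_setequal(got$snp_id, rec$snp_id[want])
  }
  # two perfectly correlated SNPs: the lower-p one survives
  dup <- make_geno(matrix(rep(base, 2), 2, n, byrow = TRUE,
                          dimnames = list(c("rsA", "rsB"), sprintf("P%03d", 1:n))))
  rec2 <- data.frame(snp_id = rownames(dup$dosages), site_id = "s",
                     beta = 0.05, se = 0.01, p = c(1e-4, 1e-8), r2 = 0.1,
                     distance = 0, effect_allele = "A", other_allele = "G",
                     maf = 0.4, n = n)
  expect_equal(ld_clump(rec2, dup, 0.01)$snp_id, rownames(dup$dosages)[2])
  # r2_max = 1 keeps everything
  expect_equal(nrow(ld_clump(rec2, dup, 1.0)), 2)
})

test_that("Wald ratios and harmonisation follow the closed forms", {
  instr <- data.frame(snp_id = "rs1", site_id = "cgA", beta = 0.5, se = 0.01,
                      p = 1e-10, r2 = 0.1, distance = 0, effect_allele = "A",
                      other_allele = "G", maf = 0.3, n = 500)
  out <- data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
                    beta = 0.1, se = 0.02, p = 1e-6, n = 5e5)
  wr <- wald_ratio(instr, harmonise_outcome(instr, out))
  expect_equal(wr$beta, 0.2)
  expect_equal(wr$se, 0.04)

  # allele flip in the outcome is undone by harmonisation
  flip <- transform(out, effect_allele = "G", other_allele = "A", beta = -0.1)
  wr2 <- wald_ratio(instr, harmonise_outcome(instr, flip))
  expect_equal(wr2$beta, wr$beta)
  # double flip is the identity
  h2 <- harmonise_outcome(instr, harmonise_outcome(instr, flip))
  expect_equal(h2$beta, harmonise_outcome(instr, flip)$beta)

  # strand-complement match resolves
  comp <- transform(out, effect_allele = "T", other_allele = "C")
  expect_equal(harmonise_outcome(instr, comp)$beta, 0.1)
  # irreconcilable alleles error
  bad <- transform(out, effect_allele = "A", other_allele = "C")
  expect_error(harmonise_outcome(instr, bad), "harmonise")

  expect_equal(wald_ratio(instr, transform(out, beta = 0))$beta, 0)
  expect_error(wald_ratio(transform(instr, beta = 1e-15), out), "zero")
})

test_that("IVW equals the weighted mean of Wald ratios and handles effects models", {
  set.seed(22)
  k <- 5
  instr <- data.frame(snp_id = sprintf("rs%d", 1:k), site_id = "cgA",
                      beta = runif(k, 0.03, 0.1), se = 0.01, p = 1e-9,
                      r2 = 0.1, distance = 0, effect_allele = "A",
                      other_allele = "G", maf = 0.3, n = 500)
  out <- data.frame(snp = instr$snp_id, effect_allele = "A", other_allele = "G",
                    beta = 0.2 * instr$beta + rnorm(k, 0, 0.002),
                    se = runif(k, 0.002, 0.004), p = 1e-6, n = 5e5)
  fit <- ivw_mr(instr, out)
  # algebraic identity: IVW slope = sum w_i bx_i^2 WR_i / sum w_i bx_i^2
  wr <- out$beta / instr$beta
  w <- instr$beta^2 / out$se^2
  expect_lt(abs(fit$beta - sum(w * wr) / sum(w)), 1e-10)

  # two identical ratios: Q = 0 and beta equals the ratio
  i2 <- instr[1:2, ]; o2 <- out[1:2, ]
  o2$beta <- 0.25 * i2$beta; o2$se <- c(0.002, 0.003)
  f2 <- ivw_mr(i2, o2)
  expect_equal(f2$beta, 0.25, tolerance = 1e-12)
  expect_lt(f2$cochran_Q, 1e-20)

  # random-effects never shrinks the SE
  fr <- ivw_mr(instr, out, effects = "random")
  expect_gte(fr$se, fit$se)
  expect_error(ivw_mr(instr[1, ], out[1, ]), "wald_ratio")
})

test_that("Egger regression recovers slope and planted pleiotropy", {
  set.seed(23)
  k <- 8
  instr <- data.frame(snp_id = sprintf("rs%d", 1:k), site_id = "cgA",
                      beta = runif(k, 0.03, 0.12), se = 0.01, p = 1e-9,
                      r2 = 0.1, distance = 0, effect_allele = "A",
                      other_allele = "G", maf = 0.3, n = 500)
  # exactly proportional: intercept 0, slope c
  out <- data.frame(snp = instr$snp_id, effect_allele = "A", other_allele = "G",
                    beta = 0.3 * instr$beta, se = 0.003, p = 1e-6, n = 5e5)
  eg <- egger_mr(instr, out)
  expect_equal(eg$beta, 0.3, tolerance = 1e-10)
  expect_lt(abs(eg$egger_intercept), 1e-12)

  # constant pleiotropy offset appears in the intercept
  out2 <- transform(out, beta = 0.05 + 0.3 * instr$beta + rnorm(k, 0, 0.002))
  eg2 <- egger_mr(instr, out2)
  expect_lt(abs(eg2$egger_intercept - 0.05), 2 * 0.01)
  expect_error(egger_mr(instr[1:2, ], out[1:2, ]), ">= 3")
})

test_that("the Steiger test orients by explained variance with the Fisher z form", {
  same <- steiger_test(0.1, 500, 0.1, 500)
  expect_equal(same$p, 1)
  st <- steiger_test(0.1, 588, 0.001, 5e5)
  expect_equal(st$direction, "exposure->outcome")
  expect_lt(st$p, 1e-6)
  # closed form
  z <- (atanh(sqrt(0.1)) - atanh(sqrt(0.001))) / sqrt(1 / 585 + 1 / (5e5 - 3))
  expect_equal(st$z, z)
  # antisymmetry
  sw <- steiger_test(0.001, 5e5, 0.1, 588)
  expect_equal(sw$direction, "outcome->exposure")
  expect_equal(sw$p, st$p)
  expect_error(steiger_test(1, 100, 0.1, 100), "degenerate")
})

test_that("proxy lookup maximises LD and flips alleles for negative correlation", {
  set.seed(24)
  n <- 300
  base <- rbinom(n, 2, 0.4)
  dos <- rbind(target = base,
               perfect = base,
               neg = 2 - ifelse(runif(n) < 0.97, base, rbinom(n, 2, 0.4)),
               weak = rbinom(n, 2, 0.4))
  g <- make_geno(dos, ea = c("A", "C", "C", "C"), oa = c("G", "T", "T", "T"))
  self <- proxy_lookup("target", g)
  expect_equal(self$proxy_id, "target")
  expect_equal(self$r2, 1)

  best <- proxy_lookup("target", g, exclude_self = TRUE)
  expect_equal(best$proxy_id, "perfect")
  expect_equal(best$aligned_allele, "C")

  g2 <- make_geno(dos[c(1, 3, 4), ], ea = c("A", "C", "C"), oa = c("G", "T", "T"))
  rownames(g2$dosages) <- c("target", "neg", "weak")
  neg <- proxy_lookup("target", g2, exclude_self = TRUE)
  expect_equal(neg$proxy_id, "neg")
  expect_equal(neg$aligned_allele, "T")   # negative correlation flips

  g3 <- make_geno(dos[c(1, 4), ])
  rownames(g3$dosages) <- c("target", "weak")
  expect_message(none <- proxy_lookup("target", g3, exclude_self = TRUE),
                 "below threshold")
  expect_null(none)
})

test_that("the end-to-end MR pipeline flags forward chains and rejects reverse ones", {
  cfg <- sim_config(n_sites = 1500, n_genes = 40, n_snps = 60, seed = 71,
                    n_mqtl = 10, n_chains = 4, n_reverse_chains = 2,
                    mqtl_shift = 0.1, n_target_links = 3, n_mediation = 2)
  sim <- suppressWarnings(simulate_cohort(cfg))
  gw <- simulate_gwas_from_chain(sim$truth, sim$geno, 5e5, seed = 72)
  sent <- data.frame(sentinel_id = sim$truth$chains$site_id)
  res <- suppressMessages(mr_pipeline(sent, sim$ref$geno, sim$ref$meth,
                                      list(bmi = gw)))
  r <- res$results
  fwd <- sim$truth$chains$site_id[sim$truth$chains$direction == "forward"]
  rev <- sim$truth$chains$site_id[sim$truth$chains$direction == "reverse"]
  testable_fwd <- intersect(fwd, r$site_id)
  expect_gte(length(testable_fwd), 3)
  expect_true(all(r$causal[r$site_id %in% testable_fwd]))
  expect_false(any(r$causal[r$site_id %in% rev]))
  # wald iff single instrument
  expect_true(all((r$method == "wald") == (r$n_snps == 1)))
})
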