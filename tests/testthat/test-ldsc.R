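test_that("LD scores behave at the unlinked and duplicated extremes", {
  p <- tiny_panel(n = 500, m = 400, seed = 1)
  lds <- compute_ld_scores(p)
  expect_lt(abs(mean(lds$L2) - 1), 0.05)      # adjusted estimator is unbiased
  expect_true(all(lds$L2 >= 1 - 400 / (500 - 2)))
  # two perfectly duplicated, isolated SNPs each score exactly 2
  set.seed(2)
  g <- rbinom(300, 2, 0.4)
  dup <- manual_panel(cbind(g, g), bp = c(1000L, 2000L))
  expect_equal(compute_ld_scores(dup)$L2, c(2, 2))
})

test_that("within-block LD scores peak in the block interior", {
  for (s in 1:5) {
    p <- tiny_panel(n = 400, m = 40, seed = 10 + s, rho = 0.9, block = 20)
    lds <- compute_ld_scores(p)   # rows already in block/position order
    for (b in 0:1) {
      l <- lds$L2[b * 20 + (1:20)]
      expect_gt(max(l[8:13]), max(l[c(1, 20)]))
    }
  }
})

test_that("LD scores are invariant to SNP order and strand relabeling", {
  p <- tiny_panel(n = 200, m = 120, seed = 3, rho = 0.6)
  lds <- compute_ld_scores(p)
  set.seed(99)
  perm <- sample.int(120)
  p2 <- subset_panel(p, variants = perm)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  p2$variants$A1 <- comp[p2$variants$A1]
  p2$variants$A2 <- comp[p2$variants$A2]
  lds2 <- compute_ld_scores(p2)
  expect_equal(lds2$L2[match(lds$SNP, lds2$SNP)], lds$L2, tolerance = 1e-12)
  expect_error(compute_ld_scores(p, window_bp = 0), "window")
})

test_that("flat chi-square input gives zero heritability", {
  p <- tiny_panel(n = 300, m = 500, seed = 4)
  lds <- compute_ld_scores(p)
  ss <- data.frame(SNP = p$variants$SNP, A1 = p$variants$A1,
                   A2 = p$variants$A2, N = 1000, Z = 1)
  fit <- ldsc_h2(ss, lds)
  expect_equal(fit$slope, 0, tolerance = 1e-10)
  expect_equal(fit$h2_obs, 0, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_error(ldsc_h2(ss[1:100, ], lds), "200")
})

test_that("null summary statistics yield h2 near zero, intercept near one", {
  p <- tiny_panel(n = 800, m = 3000, seed = 5, rho = 0.5)
  set.seed(6)
  y <- rnorm(800)
  assoc <- association_scan(p, y)
  lds <- compute_ld_scores(p)
  fit <- ldsc_h2(assoc_to_sumstats(assoc), lds)
  expect_lt(abs(fit$h2_obs), 2 * fit$se_h2 + 0.01)
  expect_lt(abs(fit$intercept - 1), 2 * fit$se_intercept + 0.01)
})

test_that("identical summary statistics give rg = 1; independents give 0", {
  p <- tiny_panel(n = 1200, m = 3000, seed = 7, rho = 0.9, block = 25)
  lds <- compute_ld_scores(p)
  pr <- simulate_trait_pair(p, h2 = c(0.6, 0.6), rg = 0, n_causal = 3000,
                            seed = 8)
  sa <- assoc_to_sumstats(association_scan(p, pr$y1))
  sb <- assoc_to_sumstats(association_scan(p, pr$y2))
  same <- ldsc_rg(sa, sa, lds)
  expect_equal(same$rg, 1, tolerance = 1e-9)
  indep <- ldsc_rg(sa, sb, lds)
  expect_lt(abs(indep$rg), 2 * indep$se_rg + 0.1)
  # allele harmonization: swapping B's alleles and flipping Z changes nothing
  sb_fl <- sb
  sb_fl$A1 <- sb$A2; sb_fl$A2 <- sb$A1; sb_fl$Z <- -sb$Z
  expect_equal(ldsc_rg(sa, sb_fl, lds)$rg, indep$rg, tolerance = 1e-12)
  # non-positive h2 is reported as non-estimable with a reason
  szero <- sa; szero$Z <- rep(c(-0.01, 0.01), length.out = nrow(sa))
  ne <- ldsc_rg(szero, sb, lds)
  expect_true(is.na(ne$rg))
  expect_match(ne$reason, "not estimable")
})

test_that("interaction scan is calibrated under the null and finds planted GxE", {
  p <- tiny_panel(n = 600, m = 2000, seed = 9)
  set.seed(10)
  E <- rnorm(600)
  y <- rnorm(600)
  ss <- interaction_scan(p, y, E)
  expect_lt(abs(mean(ss$Z^2, na.rm = TRUE) - 1), 0.08)
  expect_error(interaction_scan(p, y, rep(1, 600)), "constant")
  hits <- 0L
  for (r in 1:5) {
    p2 <- tiny_panel(n = 500, m = 300, seed = 20 + r)
    set.seed(30 + r)
    E2 <- rnorm(500)
    g <- scale(p2$dosage[, 123])
    y2 <- 0.35 * g * E2 + rnorm(500)
    ss2 <- interaction_scan(p2, y2, E2)
    if (which.max(ss2$Z^2) == 123) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  # oracle check of one interaction fit against lm()
  set.seed(40)
  covs <- cbind(rnorm(500))
  y3 <- rnorm(500)
  ss3 <- interaction_scan(p2, y3, E2, covariates = covs)
  g <- as.numeric(p2$dosage[, 7])
  Ez <- as.numeric(scale(E2))
  o <- summary(lm(y3 ~ covs + Ez + g + I(g * Ez)))$coefficients
  expect_equal(ss3$Z[7], o["I(g * Ez)", 3], tolerance = 1e-8)
})

test_that("GxEsum inverts its expectation model exactly", {
  p <- tiny_panel(n = 400, m = 600, seed = 11)
  lds <- compute_ld_scores(p)
  # null point: chi2 identically 1 -> both variances exactly zero
  ss <- data.frame(SNP = p$variants$SNP, A1 = p$variants$A1,
                   A2 = p$variants$A2, N = 400, Z = 1)
  fit <- gxesum_fit(ss, lds)
  expect_equal(fit$sigma2_g1, 0, tolerance = 1e-10)
  expect_equal(fit$sigma2_tau1, 0, tolerance = 1e-10)
  expect_false(fit$boundary)
  # algebraic identity: the fitted line reproduces E[chi2 | l] with
  # weighted residuals orthogonal to the design
  set.seed(12)
  ss$Z <- sqrt(rchisq(600, df = 1))
  fit2 <- gxesum_fit(ss, lds)
  d <- merge(ss, lds, by = "SNP")
  keep <- d$Z^2 <= max(80, 0.001 * 400)
  w <- 1 / pmax(d$L2[keep], 1)
  r <- d$Z[keep]^2 - (fit2$intercept + fit2$slope * d$L2[keep])
  expect_lt(abs(sum(w * r)), 1e-8)
  expect_lt(abs(sum(w * r * d$L2[keep])), 1e-8)
  # inversion identities
  expect_equal(fit2$sigma2_g1, fit2$slope * fit2$M / fit2$N)
  expect_equal(fit2$sigma2_tau1,
               (fit2$intercept - 1) / 2 - fit2$sigma2_g1)
})

test_that("jackknife SEs track the replicate spread of LDSC estimates", {
  h2 <- se <- numeric(8)
  for (r in 1:8) {
    p <- tiny_panel(n = 500, m = 1500, seed = 50 + r, rho = 0.4)
    tr <- simulate_trait(p, 0.4, seed = 60 + r)
    assoc <- association_scan(p, tr$y)
    lds <- compute_ld_scores(p)
    fit <- ldsc_h2(assoc_to_sumstats(assoc), lds)
    h2[r] <- fit$h2_obs; se[r] <- fit$se_h2
  }
  ratio <- mean(se) / sd(h2)
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("summary-statistic and LD-score files round-trip", {
  p <- tiny_panel(n = 100, m = 60, seed = 13)
  lds <- compute_ld_scores(p)
  pre <- file.path(tempdir(), "lds")
  write_ldscore(lds, pre)
  lds2 <- read_ldscore(pre)
  expect_equal(lds2$L2, lds$L2, tolerance = 1e-12)
  expect_equal(attr(lds2, "M"), 60)
  ss <- data.frame(SNP = p$variants$SNP, A1 = p$variants$A1,
                   A2 = p$variants$A2, N = 100L, Z = rnorm(60))
  write_sumstats(ss, paste0(pre, ".ss"))
  ss2 <- read_sumstats(paste0(pre, ".ss"))
  expect_equal(ss2$Z, ss$Z, tolerance = 1e-12)
})
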