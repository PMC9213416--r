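test_that("association statistics are internally consistent", {
  p <- tiny_panel(n = 300, m = 120, seed = 1)
  set.seed(2)
  y <- rnorm(300) + 0.5 * scale(p$dosage[, 1])
  assoc <- association_scan(p, y)
  expect_equal(assoc$STAT, assoc$BETA / assoc$SE, tolerance = 1e-6)
  p_re <- 2 * pt(-abs(assoc$STAT), df = assoc$NMISS - 2)
  expect_equal(assoc$P, p_re, tolerance = 1e-6)
  expect_true(all(assoc$NMISS <= 300))
  expect_lt(assoc$P[1], 1e-4)
})

test_that("a perfect predictor returns its defining coefficient", {
  set.seed(3)
  g <- rbinom(120, 2, 0.5)
  panel <- manual_panel(cbind(g, rbinom(120, 2, 0.3)))
  assoc <- association_scan(panel, g / 2)
  expect_equal(assoc$BETA[1], 0.5, tolerance = 1e-12)
  expect_lt(assoc$P[1], 1e-200)
})

test_that("per-SNP fits agree with lm/glm oracles, including missingness", {
  p <- tiny_panel(n = 200, m = 25, seed = 4, missing_rate = 0.05)
  set.seed(5)
  covs <- cbind(age = rnorm(200), sexm = rbinom(200, 1, 0.5))
  y <- rnorm(200)
  assoc <- association_scan(p, y, covariates = covs, model = "linear")
  yb <- rbinom(200, 1, 0.3)
  assoc_l <- association_scan(p, yb, covariates = covs, model = "logistic")
  for (j in c(1, 7, 25)) {
    g <- p$dosage[, j]
    ok <- !is.na(g)
    o <- summary(lm(y[ok] ~ covs[ok, ] + g[ok]))$coefficients
    expect_equal(assoc$BETA[j], o["g[ok]", 1], tolerance = 1e-8)
    expect_equal(assoc$SE[j], o["g[ok]", 2], tolerance = 1e-8)
    expect_equal(assoc$NMISS[j], sum(ok))
    ol <- summary(glm(yb[ok] ~ covs[ok, ] + g[ok],
                      family = binomial()))$coefficients
    expect_equal(assoc_l$BETA[j], ol["g[ok]", 1], tolerance = 1e-6)
    expect_equal(assoc_l$SE[j], ol["g[ok]", 2], tolerance = 1e-6)
  }
  # constant covariate (sex in a sex-restricted scan) is dropped, not fatal
  assoc_c <- association_scan(p, y, covariates = cbind(sexm = rep(1, 200) * 0))
  expect_false("sexm" %in% attr(assoc_c, "covariates"))
})

test_that("null scans produce uniform p-values", {
  p <- tiny_panel(n = 500, m = 2000, seed = 6)
  set.seed(7)
  y <- rnorm(500)
  assoc <- association_scan(p, y)
  ks <- suppressWarnings(ks.test(assoc$P, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("inflation rescaling follows the 1000-case formula", {
  expect_equal(lambda_1000(1, 123, 45678), 1)
  expect_equal(lambda_1000(1.1, 5e4, 5e4), 1.002)
  expect_error(lambda_1000(1.1, 0, 100), "positive")
  p <- tiny_panel(n = 300, m = 150, seed = 8)
  set.seed(9)
  y <- rbinom(300, 1, 0.3)
  assoc <- association_scan(p, y)
  infl <- genomic_inflation(assoc)
  expect_equal(infl$lambda_observed,
               median(assoc$STAT^2) / qchisq(0.5, 1))
  expect_equal(infl$n_cases, sum(y))
  expect_equal(nrow(infl$qq), 150)
  expect_error(genomic_inflation(assoc[1:50, ], 10, 10), "100 SNPs")
})

test_that("clumping matches brute-force grouping and ignores row order", {
  # three significant SNPs: 1 and 2 in strong LD, 3 unlinked -> 2 loci
  set.seed(10)
  g1 <- rbinom(400, 2, 0.5)
  g2 <- g1; flip <- sample.int(400, 12); g2[flip] <- rbinom(12, 2, 0.5)
  g3 <- rbinom(400, 2, 0.5)
  panel <- manual_panel(cbind(g1, g2, g3, rbinom(400, 2, 0.4)),
                        bp = c(1000L, 2000L, 500000L, 900000L))
  assoc <- data.frame(CHR = 1L, BP = panel$variants$BP,
                      SNP = panel$variants$SNP, A1 = "A", A2 = "G",
                      P = c(1e-10, 1e-9, 1e-8, 0.5),
                      BETA = 0.1, SE = 0.01, STAT = 10,
                      NMISS = 400L, stringsAsFactors = FALSE)
  loci <- clump_loci(assoc, panel, p_threshold = 5e-8)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$SNP[1], "m0001")             # lowest p leads
  expect_true("m0002" %in% loci$members[[1]])
  shuffled <- assoc[c(3, 1, 4, 2), ]
  loci2 <- clump_loci(shuffled, panel, p_threshold = 5e-8)
  expect_identical(loci$SNP, loci2$SNP)
  none <- clump_loci(assoc[assoc$P > 1e-3, ], panel)
  expect_equal(nrow(none), 0)
})

test_that("a planted multi-locus architecture is recovered exactly", {
  p <- tiny_panel(n = 1200, m = 400, seed = 11, rho = 0.8, block = 20)
  causal <- c(30, 130, 230, 330)               # one per distinct block
  set.seed(12)
  y <- rowSums(scale(p$dosage[, causal])) * 0.28 + rnorm(1200)
  assoc <- association_scan(p, y)
  loci <- clump_loci(assoc, p, p_threshold = 5e-8, clump_r2 = 0.05)
  expect_equal(nrow(loci), 4)
  lead_block <- (match(loci$SNP, p$variants$SNP) - 1) %/% 20
  expect_setequal(lead_block, (causal - 1) %/% 20)
})

test_that("GWAS meta-analysis follows inverse-variance algebra", {
  p <- tiny_panel(n = 250, m = 60, seed = 13)
  set.seed(14)
  y <- rnorm(250)
  assoc <- association_scan(p, y)
  expect_identical(meta_analyse_gwas(list(assoc)), assoc)
  m2 <- meta_analyse_gwas(list(assoc, assoc))
  expect_equal(m2$BETA, assoc$BETA, tolerance = 1e-12)
  expect_equal(m2$SE, assoc$SE / sqrt(2), tolerance = 1e-12)
  m4 <- meta_analyse_gwas(list(assoc, assoc, assoc, assoc))
  expect_equal(m4$SE, assoc$SE / 2, tolerance = 1e-12)
  # allele harmonization: swapped alleles with flipped sign meta to the same
  flipped <- assoc
  flipped$A1 <- assoc$A2; flipped$A2 <- assoc$A1; flipped$BETA <- -assoc$BETA
  mh <- meta_analyse_gwas(list(assoc, flipped))
  expect_equal(mh$BETA, assoc$BETA, tolerance = 1e-12)
  # irreconcilable alleles are dropped with a log entry
  bad <- assoc
  bad$A1[1] <- "T"; bad$A2[1] <- "C"
  mb <- meta_analyse_gwas(list(assoc, bad))
  expect_true(assoc$SNP[1] %in% attr(mb, "dropped"))
  # stouffer mode returns finite statistics
  ms <- meta_analyse_gwas(list(assoc, assoc), method = "stouffer")
  expect_true(all(is.finite(ms$STAT)))
})

test_that("grouped-phenotype scans outpower subtype meta-analysis on shared loci", {
  # two subtypes sharing the same causal variants: scanning the union
  # phenotype should find at least as many of the shared hits as the
  # per-subtype meta-analysis, in most replicates
  wins <- 0L
  for (r in 1:6) {
    p <- tiny_panel(n = 1500, m = 150, seed = 20 + r)
    set.seed(40 + r)
    shared <- scale(p$dosage[, 10])
    l1 <- 0.22 * shared + rnorm(1500)
    l2 <- 0.22 * shared + rnorm(1500)
    y1 <- as.integer(l1 > quantile(l1, 0.8))
    y2 <- as.integer(l2 > quantile(l2, 0.8))
    grouped <- as.integer(y1 | y2)
    sg <- association_scan(p, grouped)
    meta <- meta_analyse_gwas(list(association_scan(p, y1),
                                   association_scan(p, y2)))
    thr <- 1e-6
    if (sum(sg$P < thr, na.rm = TRUE) >= sum(meta$P < thr, na.rm = TRUE))
      wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
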