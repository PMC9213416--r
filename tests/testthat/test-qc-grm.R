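test_that("HWE exact mid-p matches brute-force enumeration", {
  # independent oracle: enumerate P(het | allele count) directly from the
  # closed-form conditional distribution
  hwe_brute <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    rare <- 2 * min(n_aa, n_bb) + n_ab
    hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
    logp <- vapply(hets, function(h) {
      hr <- (rare - h) / 2; hc <- n - h - hr
      h * log(2) + lfactorial(n) - lfactorial(hr) - lfactorial(hc) -
        lfactorial(h) + lfactorial(rare) + lfactorial(2 * n - rare) -
        lfactorial(2 * n)
    }, numeric(1))
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    obs <- pr[match(n_ab, hets)]
    sum(pr[pr < obs]) + 0.5 * sum(pr[pr == obs])
  }
  cases <- rbind(c(25, 50, 25), c(10, 10, 80), c(0, 5, 95), c(40, 20, 40),
                 c(3, 1, 96), c(0, 0, 50))
  for (i in seq_len(nrow(cases)))
    expect_equal(hwe_midp(cases[i, 1], cases[i, 2], cases[i, 3]),
                 hwe_brute(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-10)
  # the in-equilibrium configuration is comfortably retained at 1e-7
  expect_gt(hwe_midp(25, 50, 25), 1e-7)
})

test_that("QC cascade removes the right variants and is idempotent", {
  n <- 100
  set.seed(1)
  good <- replicate(6, rbinom(n, 2, 0.3))
  mono <- rep(2L, n)                       # monomorphic -> MAF filter
  hwe_bad <- rep(1L, n)                    # all-het -> HWE filter
  dosage <- cbind(good, mono, hwe_bad)
  panel <- manual_panel(dosage,
                        a1 = c(rep("A", 6), "A", "A"),
                        a2 = c(rep("G", 6), "G", "G"))
  panel$variants$info[3] <- 0.4            # INFO filter
  res <- apply_qc(panel, qc_thresholds())
  expect_equal(unname(res$report[c("info", "maf", "hwe")]), c(1L, 1L, 1L))
  expect_equal(nrow(res$panel$variants), 5)
  # idempotence
  res2 <- apply_qc(res$panel, qc_thresholds())
  expect_identical(res2$panel$dosage, res$panel$dosage)
  expect_true(all(res2$report == 0))
})

test_that("call-rate, ambiguous and duplicate filters work", {
  set.seed(2)
  dosage <- replicate(10, rbinom(60, 2, 0.4))
  dosage[1, 1:8] <- NA                    # sample 1: 80% missing in 10 SNPs
  panel <- manual_panel(dosage, a1 = c(rep("A", 8), "A", "C"),
                        a2 = c(rep("G", 8), "T", "G"))
  # SNP 9 is A/T ambiguous, SNP 10 is C/G ambiguous
  panel$variants$BP[2] <- panel$variants$BP[1]   # duplicate position+alleles
  res <- apply_qc(panel, qc_thresholds())
  expect_equal(unname(res$report["sample_call_rate"]), 1L)
  expect_equal(unname(res$report["ambiguous"]), 2L)
  expect_equal(unname(res$report["duplicate"]), 1L)
  expect_false("s001" %in% res$panel$sample_ids)
})

test_that("all-pass panel is returned unchanged with an all-zero report", {
  p <- tiny_panel(n = 80, m = 40, seed = 3, maf_range = c(0.2, 0.5))
  res <- apply_qc(p, qc_thresholds())
  expect_identical(res$panel$dosage, p$dosage)
  expect_true(all(res$report == 0))
})

test_that("GRM matches its defining formula", {
  # hand example: one SNP with p = 0.5, both samples carry dosage 2
  panel <- manual_panel(matrix(c(2L, 2L), 2, 1), maf = 0.5)
  g <- compute_grm(panel, freq = 0.5)
  expect_equal(unname(g$A), matrix(2, 2, 2))
  # oracle equivalence: A = Xs Xs' / M with explicit standardization
  p <- tiny_panel(n = 60, m = 90, seed = 4)
  g <- compute_grm(p)
  pf <- colMeans(p$dosage) / 2
  Xs <- sweep(sweep(p$dosage, 2, 2 * pf), 2, sqrt(2 * pf * (1 - pf)), "/")
  expect_lt(max(abs(g$A - tcrossprod(Xs) / 90)), 1e-10)
  expect_identical(g$A, t(g$A))
  # duplicated sample: off-diagonal equals the original diagonal
  p2 <- p
  p2$dosage <- rbind(p$dosage, p$dosage[1, ])
  p2$sample_ids <- c(p$sample_ids, "dup")
  p2$sex <- c(p$sex, p$sex[1])
  g2 <- compute_grm(p2, freq = pf)
  expect_equal(g2$A[1, 61], g2$A[1, 1])
  # zero-variance SNP raises a named error
  p3 <- manual_panel(cbind(rbinom(40, 2, 0.5), rep(0L, 40)))
  expect_error(compute_grm(p3), "zero-variance")
})

test_that("random HWE panels give a calibrated GRM", {
  p <- tiny_panel(n = 400, m = 3000, seed = 6)
  g <- compute_grm(p)
  expect_lt(abs(mean(g$A[upper.tri(g$A)])), 0.01)
  expect_gt(mean(diag(g$A)), 0.95)
  expect_lt(mean(diag(g$A)), 1.05)
})

test_that("relatedness pruning removes exactly one member per close pair", {
  A <- diag(4)
  g <- manual_grm(A)
  expect_identical(prune_related(g, 0.05), g$sample_ids)  # nothing related
  A2 <- diag(4); A2[1, 2] <- A2[2, 1] <- 0.5
  kept <- prune_related(manual_grm(A2), 0.05)
  expect_length(kept, 3)
  expect_length(intersect(kept, c("s001", "s002")), 1)
  # clique of three mutually related samples: brute force over all removal
  # orders shows one sample always survives
  A3 <- diag(5)
  A3[1:3, 1:3] <- 0.5; diag(A3) <- 1
  kept <- prune_related(manual_grm(A3), 0.05)
  expect_length(intersect(kept, c("s001", "s002", "s003")), 1)
  expect_true(all(c("s004", "s005") %in% kept))
  # post-hoc invariant on a random GRM
  p <- tiny_panel(n = 100, m = 150, seed = 7)
  g <- compute_grm(p)
  kept <- prune_related(g, 0.1)
  i <- match(kept, g$sample_ids)
  expect_lte(max(g$A[i, i][upper.tri(g$A[i, i])]), 0.1)
  expect_error(prune_related(g, 0), "cutoff")
})

test_that("PC outlier filter flags planted population outliers only", {
  # many more SNPs than samples so the outlier eigenvalue separates from the
  # Marchenko-Pastur bulk
  p <- tiny_panel(n = 100, m = 5000, seed = 8, maf_range = c(0.2, 0.4))
  # plant one sample drawn from frequencies shifted by +0.2 on all SNPs
  set.seed(9)
  shifted <- rbinom(5000, 2, pmin(p$variants$maf + 0.2, 0.95))
  p$dosage[100, ] <- as.integer(shifted)
  g <- compute_grm(p)
  res <- pc_outlier_filter(g, n_pcs = 5, sd_limit = 6)
  expect_true("id000100" %in% res$removed)
  expect_false(any(sprintf("id%06d", 1:99) %in% res$removed))
  # a homogeneous panel loses nobody at 6 SD
  p0 <- tiny_panel(n = 100, m = 1000, seed = 18)
  res0 <- pc_outlier_filter(compute_grm(p0), n_pcs = 5, sd_limit = 6)
  expect_length(res0$removed, 0)
  # infinite limit keeps everyone
  res2 <- pc_outlier_filter(g, n_pcs = 5, sd_limit = Inf)
  expect_identical(res2$kept, g$sample_ids)
  expect_error(pc_outlier_filter(g, n_pcs = 101), "rank")
})

test_that("discordance filter removes samples with flipped genotypes", {
  p <- tiny_panel(n = 60, m = 300, seed = 10)
  q <- p
  set.seed(13)
  flip <- sample.int(300, 30)                      # 10% of sample 1 entries
  q$dosage[1, flip] <- (q$dosage[1, flip] + 1L) %% 3L
  res <- discordance_filter(p, q, max_rate = 0.05)
  expect_false("id000001" %in% res$kept_samples)
  expect_length(res$kept_samples, 59)
  ident <- discordance_filter(p, p, max_rate = 0.05)
  expect_length(ident$kept_samples, 60)
  expect_length(ident$kept_variants, 300)
  disjoint <- tiny_panel(n = 5, m = 5, seed = 99)
  disjoint$sample_ids <- paste0("x", disjoint$sample_ids)
  disjoint$variants$SNP <- paste0("x", disjoint$variants$SNP)
  expect_error(discordance_filter(p, disjoint, max_rate = 0.05), "overlap")
})

test_that("PLINK and GCTA GRM files round-trip", {
  p <- tiny_panel(n = 25, m = 40, seed = 11, missing_rate = 0.05)
  pre <- file.path(tempdir(), "rt")
  write_plink(p, pre)
  p2 <- read_plink(pre)
  expect_identical(p2$dosage, p$dosage)
  expect_identical(p2$sample_ids, p$sample_ids)
  expect_identical(p2$sex, p$sex)
  expect_identical(p2$variants[, c("CHR", "BP", "SNP", "A1", "A2")],
                   p$variants[, c("CHR", "BP", "SNP", "A1", "A2")])
  g <- compute_grm(tiny_panel(n = 30, m = 100, seed = 12))
  write_grm_gcta(g, pre)
  g2 <- read_grm_gcta(pre)
  expect_identical(g2$sample_ids, g$sample_ids)
  expect_equal(g2$M, g$M)
  expect_lt(max(abs(g2$A - g$A)), 1e-6)   # single-precision storage
  # phenotype table round-trip with missing values
  d <- data.frame(sample_id = p$sample_ids, y = rnorm(25),
                  status = c(NA, rbinom(24, 1, 0.5)))
  write_pheno(d, paste0(pre, ".phen"))
  d2 <- read_pheno(paste0(pre, ".phen"))
  expect_equal(d2$y, d$y)
  expect_equal(d2$status, d$status)
})
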