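test_that("identity GRM leaves only the total variance identified", {
  p <- tiny_panel(n = 80, m = 30, seed = 1)
  g <- manual_grm(diag(80), M = 30L)
  set.seed(1)
  X <- cbind(rnorm(80))
  y <- 2 + 0.5 * X[, 1] + rnorm(80, sd = 2)
  fit <- reml_fit(y, g, covariates = X)
  expect_true("non-identified split" %in% fit$flags)
  res <- lm(y ~ X)
  expect_equal(fit$sigma2_total, sum(resid(res)^2) / (80 - 2),
               tolerance = 1e-10)
})

test_that("REML optimum agrees with a dense likelihood grid search", {
  p <- tiny_panel(n = 200, m = 400, seed = 2)
  g <- compute_grm(p)
  tr <- simulate_trait(p, 0.5, seed = 3)
  eig <- eigen(g$A, symmetric = TRUE)
  fit <- reml_fit(tr$y, g, eig = eig)
  grid <- expand.grid(sg = seq(0.02, 1.2, by = 0.02),
                      se = seq(0.02, 1.2, by = 0.02))
  ll <- mapply(function(a, b) reml_loglik(tr$y, g, a, b, eig = eig),
               grid$sg, grid$se)
  best <- grid[which.max(ll), ]
  expect_lt(abs(fit$sigma2_g - best$sg), 0.02 + 1e-9)
  expect_lt(abs(fit$sigma2_e - best$se), 0.02 + 1e-9)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("permuting the phenotype against the GRM nulls the estimate", {
  p <- tiny_panel(n = 500, m = 1000, seed = 4)
  g <- compute_grm(p)
  tr <- simulate_trait(p, 0.5, seed = 5)
  set.seed(6)
  fit <- reml_fit(sample(tr$y), g)
  expect_lt(fit$h2_obs, 2 * fit$se_h2 + 0.02)
})

test_that("REML errors on misaligned or degenerate inputs", {
  p <- tiny_panel(n = 60, m = 40, seed = 7)
  g <- compute_grm(p)
  expect_error(reml_fit(rnorm(30), g), "n >= 50|aligned")
  expect_error(reml_fit(rnorm(60), g,
                        covariates = cbind(rep(1, 60))), "singular")
})

test_that("liability transformation follows the threshold-model formula", {
  expect_equal(liability_multiplier(0.5), pi / 2, tolerance = 1e-9)
  # h2 = 0 maps to 0
  conv <- observed_to_liability(0, K = 0.1, se = 0)
  expect_equal(conv$h2_liability, 0)
  # general K != P form
  K <- 0.05; P <- 0.3
  z <- dnorm(qnorm(1 - K))
  expect_equal(liability_multiplier(K, P),
               K^2 * (1 - K)^2 / (P * (1 - P) * z^2))
  # strictly increasing in h2_obs, continuous in K
  h <- seq(0, 0.5, by = 0.05)
  out <- vapply(h, function(x)
    observed_to_liability(x, K = 0.1, se = 0.01)$h2_liability, numeric(1))
  expect_true(all(diff(out) > 0))
  Ks <- seq(0.01, 0.99, by = 0.001)
  mult <- vapply(Ks, liability_multiplier, numeric(1))
  expect_lt(max(abs(diff(mult)) / mult[-1]), 0.1)    # no jumps on a fine grid
  expect_error(liability_multiplier(0), "K")
  expect_error(liability_multiplier(0.5, 1), "P")
})

test_that("bivariate REML handles degenerate, null and correlated pairs", {
  p <- tiny_panel(n = 800, m = 800, seed = 8)
  g <- compute_grm(p)
  eig <- eigen(g$A, symmetric = TRUE)
  tr <- simulate_trait(p, 0.4, seed = 9)
  # an exact copy: covariance sits on the PD boundary, rg = 1
  dup <- bivariate_reml(tr$y, tr$y, g, eig = eig)
  expect_equal(dup$rg, 1)
  # independent architectures: rg within 2 SE of 0
  tr2 <- simulate_trait(p, 0.4, seed = 10)
  ind <- bivariate_reml(tr$y, tr2$y, g, eig = eig)
  expect_lt(abs(ind$rg_raw), 2 * ind$se_rg + 0.05)
  # correlated pair: recovery within 2 SE, LRT rejects independence
  pr <- simulate_trait_pair(p, h2 = c(0.4, 0.4), rg = 0.5, seed = 11)
  cor_fit <- bivariate_reml(pr$y1, pr$y2, g, eig = eig, lrt = TRUE)
  expect_lt(abs(cor_fit$rg_raw - 0.5), 2 * cor_fit$se_rg)
  expect_lt(cor_fit$lrt$p, 0.05)
  expect_equal(cor_fit$lrt$df, 2)
  # a trait orthogonal to the genetic space drives sigma2_g to the floor,
  # making rg undefined with a reason
  set.seed(12)
  anti <- as.numeric(eig$vectors[, 401:800] %*% rnorm(400))
  flat <- bivariate_reml(anti, pr$y1, g, eig = eig)
  expect_true(is.na(flat$rg))
  expect_match(flat$reason, "boundary|not estimable")
})

test_that("stratified GxE flags heterogeneous strata and not permuted ones", {
  p <- tiny_panel(n = 700, m = 500, seed = 13)
  g <- compute_grm(p)
  expect_error(gxe_stratified(rnorm(700), rep(1, 700), g), "constant")
  yz <- c(rep(0, 350), rep(1, 350))
  expect_error(gxe_stratified(yz, c(rep("a", 350), rep("b", 350)), g),
               "zero cases")
  # permuted environment labels do not create spurious GxE (rg stays near 1)
  gx <- simulate_gxe_strata(p, h2 = 0.6, rg_strata = 1, seed = 14)
  set.seed(15)
  fit <- gxe_stratified(gx$y, sample(gx$env), g)
  expect_gt(fit$rg_raw, 1 - 2.5 * fit$se_rg)
  # and a genuinely heterogeneous architecture is detected
  gx2 <- simulate_gxe_strata(p, h2 = 0.6, rg_strata = 0.1, seed = 16)
  fit2 <- gxe_stratified(gx2$y, gx2$env, g)
  expect_lt(fit2$p_rg1, 0.05)
})

test_that("the dense engine reproduces the eigen engine on a shared design", {
  # same bivariate model fit through both code paths must agree
  p <- tiny_panel(n = 150, m = 200, seed = 17)
  g <- compute_grm(p)
  pr <- simulate_trait_pair(p, h2 = c(0.5, 0.5), rg = 0.7, seed = 18)
  bv <- bivariate_reml(pr$y1, pr$y2, g)
  n <- 150
  Blist <- list(
    rbind(cbind(g$A, matrix(0, n, n)), matrix(0, n, 2 * n)),
    rbind(cbind(matrix(0, n, n), g$A), cbind(g$A, matrix(0, n, n))),
    rbind(matrix(0, n, 2 * n), cbind(matrix(0, n, n), g$A)),
    diag(c(rep(1, n), rep(0, n))),
    rbind(cbind(matrix(0, n, n), diag(n)), cbind(diag(n), matrix(0, n, n))),
    diag(c(rep(0, n), rep(1, n))))
  X <- rbind(cbind(1, 0), cbind(0, 1))[rep(1:2, each = n), ]
  dense <- grouph2:::reml_ai_dense(c(pr$y1, pr$y2), X, Blist,
                                   start = bv$theta)
  expect_equal(dense$theta, bv$theta, tolerance = 1e-3)
  expect_lt(abs(dense$loglik - bv$loglik), 1e-3)
})

test_that("Fisher/IVW split meta-analysis matches closed forms", {
  m <- split_meta(c(0.1, 0.2), c(0.05, 0.05), c(0.05, 0.05))
  expect_equal(m$fisher_stat, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(m$fisher_stat, 11.98293, tolerance = 1e-5)
  expect_equal(m$p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(m$estimate, 0.15)            # equal SEs pool to the mean
  expect_equal(m$se, 0.05 / sqrt(2))
  expect_lte(m$se, min(0.05, 0.05))
  all1 <- split_meta(c(0, 0), c(1, 1), c(1, 1))
  expect_equal(all1$fisher_stat, 0)
  expect_equal(all1$p, 1)
  expect_warning(split_meta(c(0, 0), c(1, 1), c(0, 0.5)), "0")
  expect_error(split_meta(0.1, 0.05, 0.05), "k >= 2|length")
})

test_that("split-sample GREML pools back to the full-data estimate", {
  p <- tiny_panel(n = 600, m = 800, seed = 19)
  g <- compute_grm(p)
  tr <- simulate_trait(p, 0.5, seed = 20)
  full <- reml_fit(tr$y, g)
  expect_identical(split_sizes(197365, 2), c(98682L, 98683L))
  expect_equal(sum(split_sizes(1000, 3)), 1000L)
  expect_lte(max(split_sizes(1000, 3)) - min(split_sizes(1000, 3)), 1L)
  expect_error(split_sizes(100, 1), "at least 2")
  run <- split_sample_runner(tr$y, g, k = 2, seed = 21)
  expect_lt(abs(run$meta$estimate - full$h2_obs), 2 * run$meta$se)
  expect_error(split_sample_runner(tr$y, g, k = 20, seed = 1), "minimum n")
})
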