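#' Compute LD scores with the small-sample-adjusted r2 estimator
#'
#' The LD score of SNP j is 1 (the self term) plus the sum, over SNPs within
#' \code{window_bp} on the same chromosome, of the adjusted squared
#' correlation r2_adj = r2 - (1 - r2) / (n - 2), which is unbiased for zero
#' at unlinked pairs. Missing dosages are mean-imputed for the correlation
#' computation. Scores are invariant to SNP input order and to strand
#' relabeling of alleles.
#'
#' @param panel a QC'd genotype_panel.
#' @param window_bp window half-width in base pairs (default 1 Mb).
#' @return data.frame with CHR, SNP, BP, L2.
#' @export
compute_ld_scores <- function(panel, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive")
  v <- panel$variants
  n <- length(panel$sample_ids)
  m <- nrow(v)
  l2 <- rep(1, m)
  ord <- order(v$CHR, v$BP)
  for (cc in unique(v$CHR[ord])) {
    idx <- ord[v$CHR[ord] == cc]
    Xs <- scale(standardize_dosages(panel$dosage[, idx, drop = FALSE],
                                    freq = v$maf[idx]))
    bp <- v$BP[idx]
    mc <- length(idx)
    chunk <- 1000L
    for (a in seq(1, mc, by = chunk)) {
      b <- min(a + chunk - 1L, mc)
      w1 <- findInterval(bp[a] - window_bp - 1, bp) + 1L
      w2 <- findInterval(bp[b] + window_bp, bp)
      r <- crossprod(Xs[, a:b, drop = FALSE],
                     Xs[, w1:w2, drop = FALSE]) / (n - 1)
      r2 <- r^2
      r2a <- r2 - (1 - r2) / (n - 2)
      # zero out self pairs and pairs beyond the window
      dist <- abs(outer(bp[a:b], bp[w1:w2], "-"))
      r2a[dist > window_bp] <- 0
      self <- cbind(seq_len(b - a + 1L), (a:b) - w1 + 1L)
      r2a[self] <- 0
      l2[idx[a:b]] <- 1 + rowSums(r2a)
    }
  }
  data.frame(CHR = v$CHR, SNP = v$SNP, BP = v$BP, L2 = l2,
             stringsAsFactors = FALSE)
}

# Weighted least squares of y on x with a delete-one-block jackknife.
# Returns full-data coefficients and the B x 2 matrix of delete-block
# coefficients (intercept, slope); with intercept = FALSE the intercept is
# fixed at `offset` and only the slope is estimated.
wls_blocks <- function(x, y, w, n_blocks, intercept = TRUE, offset = 0) {
  m <- length(x)
  n_blocks <- max(2L, min(n_blocks, floor(m / 2)))
  blk <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  if (intercept) {
    D <- cbind(1, x)
  } else {
    D <- cbind(x)
    y <- y - offset
  }
  p <- ncol(D)
  XtX_b <- array(0, c(n_blocks, p, p))
  Xty_b <- matrix(0, n_blocks, p)
  for (b in seq_len(n_blocks)) {
    i <- which(blk == b)
    Db <- D[i, , drop = FALSE] * w[i]
    XtX_b[b, , ] <- crossprod(D[i, , drop = FALSE], Db)
    Xty_b[b, ] <- crossprod(Db, y[i])
  }
  XtX <- apply(XtX_b, c(2, 3), sum)
  Xty <- colSums(Xty_b)
  coef_full <- solve(XtX, Xty)
  coef_jack <- matrix(NA_real_, n_blocks, p)
  for (b in seq_len(n_blocks))
    coef_jack[b, ] <- solve(XtX - XtX_b[b, , ], Xty - Xty_b[b, ])
  if (!intercept) {
    coef_full <- c(offset, coef_full)
    coef_jack <- cbind(offset, coef_jack)
  }
  list(coef = coef_full, jack = coef_jack, n_blocks = n_blocks)
}

jackknife_se <- function(values) {
  B <- length(values)
  sqrt((B - 1) / B * sum((values - mean(values))^2))
}

ldsc_merge <- function(ss, ldscores) {
  i <- match(ss$SNP, ldscores$SNP)
  ok <- !is.na(i)
  cbind(ss[ok, , drop = FALSE], L2 = ldscores$L2[i[ok]])
}

#' LD-score regression heritability from summary statistics
#'
#' Regresses per-SNP chi-square statistics on LD scores by weighted least
#' squares (weights 1 / max(L2, 1)); the slope times M / N-bar is the
#' observed-scale SNP heritability and the intercept captures confounding.
#' Standard errors come from a delete-one-block jackknife over contiguous
#' SNP blocks (200 by default, fewer for small panels). Extreme statistics
#' (chi2 > max(80, 0.001 N)) are removed before the regression. Optionally
#' converts to the liability scale with the same K = P convention as GREML.
#'
#' @param sumstats data.frame with SNP, A1, A2, N, Z.
#' @param ldscores data.frame from [compute_ld_scores()].
#' @param M number of SNPs the heritability refers to (default: number of
#'   regression SNPs).
#' @param n_blocks jackknife blocks (default 200).
#' @param intercept estimate the intercept (TRUE) or constrain it to 1.
#' @param chisq_max outlier cutoff; default max(80, 0.001 * median N).
#' @param K population prevalence for an optional liability conversion.
#' @param P sample case proportion (defaults to K).
#' @return object of class "ldsc_fit".
#' @export
ldsc_h2 <- function(sumstats, ldscores, M = NULL, n_blocks = 200,
                    intercept = TRUE, chisq_max = NULL, K = NULL, P = NULL) {
  d <- ldsc_merge(sumstats, ldscores)
  if (nrow(d) < 200) stop("fewer than 200 SNPs after merging")
  chisq <- d$Z^2
  chisq_max <- chisq_max %||% max(80, 0.001 * stats::median(d$N))
  keep <- chisq <= chisq_max
  d <- d[keep, , drop = FALSE]; chisq <- chisq[keep]
  M <- M %||% nrow(d)
  Nbar <- mean(d$N)
  w <- 1 / pmax(d$L2, 1)
  fit <- wls_blocks(d$L2, chisq, w, n_blocks, intercept = intercept,
                    offset = 1)
  h2_of <- function(coef) coef[2] * M / Nbar
  h2 <- h2_of(fit$coef)
  h2_j <- apply(fit$jack, 1, h2_of)
  out <- list(slope = fit$coef[2], intercept = fit$coef[1],
              se_intercept = jackknife_se(fit$jack[, 1]),
              h2_obs = h2, se_h2 = jackknife_se(h2_j),
              M = M, n_snp = nrow(d), mean_chisq = mean(chisq),
              n_blocks = fit$n_blocks, Nbar = Nbar)
  out$p_h2 <- p_from_z(out$h2_obs / out$se_h2)
  if (!is.null(K)) {
    mult <- liability_multiplier(K, P %||% K)
    out$h2_liability <- h2 * mult
    out$se_h2_liability <- out$se_h2 * mult
    out$K <- K
  }
  structure(out, class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("LD-score regression\n")
  cat(sprintf("  h2 (observed) = %.4f (se %.4f); intercept = %.4f (se %.4f)\n",
              x$h2_obs, x$se_h2, x$intercept, x$se_intercept))
  if (!is.null(x$h2_liability))
    cat(sprintf("  h2 (liability, K = %.4f) = %.4f (se %.4f)\n", x$K,
                x$h2_liability, x$se_h2_liability))
  cat(sprintf("  %d SNPs (M = %d), mean chi2 = %.3f, %d jackknife blocks\n",
              x$n_snp, x$M, x$mean_chisq, x$n_blocks))
  invisible(x)
}

#' Cross-trait LD-score regression genetic correlation
#'
#' Regresses the product of per-SNP z-scores on LD scores; the slope scaled
#' by M / sqrt(N1 N2) estimates the genetic covariance and the cross-trait
#' intercept absorbs sample overlap (shared controls), which is why the
#' method is unbiased under overlapping case-control designs. rg is the
#' genetic covariance over the geometric mean of the univariate h2 estimates;
#' its SE comes from a joint delete-one-block jackknife over all three
#' regressions. Alleles are harmonized to trait A (swapped A1/A2 flips the
#' sign of Z_B; irreconcilable SNPs are dropped).
#'
#' @param ss_a,ss_b summary statistics (SNP, A1, A2, N, Z).
#' @param ldscores data.frame from [compute_ld_scores()].
#' @param M SNP count for scaling (default: regression SNPs).
#' @param n_blocks jackknife blocks.
#' @return object of class "ldsc_rg_fit"; when either univariate h2 is
#'   non-positive, rg is reported as non-estimable with the reason.
#' @export
ldsc_rg <- function(ss_a, ss_b, ldscores, M = NULL, n_blocks = 200) {
  i <- match(ss_a$SNP, ss_b$SNP)
  ok <- !is.na(i)
  a <- ss_a[ok, , drop = FALSE]
  b <- ss_b[i[ok], , drop = FALSE]
  same <- a$A1 == b$A1 & a$A2 == b$A2
  swap <- a$A1 == b$A2 & a$A2 == b$A1
  keep <- same | swap
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  zb <- ifelse(swap[keep], -b$Z, b$Z)
  d <- ldsc_merge(data.frame(SNP = a$SNP, A1 = a$A1, A2 = a$A2,
                             NA_ = a$N, NB = b$N, ZA = a$Z, ZB = zb,
                             stringsAsFactors = FALSE), ldscores)
  if (nrow(d) < 200) stop("fewer than 200 SNPs after merging")
  M <- M %||% nrow(d)
  w <- 1 / pmax(d$L2, 1)
  NAbar <- mean(d$NA_); NBbar <- mean(d$NB)
  fa <- wls_blocks(d$L2, d$ZA^2, w, n_blocks)
  fb <- wls_blocks(d$L2, d$ZB^2, w, n_blocks)
  fc <- wls_blocks(d$L2, d$ZA * d$ZB, w, n_blocks)
  h2a <- fa$coef[2] * M / NAbar
  h2b <- fb$coef[2] * M / NBbar
  gcov <- fc$coef[2] * M / sqrt(NAbar * NBbar)
  if (h2a <= 1e-8 || h2b <= 1e-8) {
    return(structure(list(
      rg = NA_real_, se_rg = NA_real_, h2 = c(h2a, h2b), gcov = gcov,
      reason = "univariate h2 estimate non-positive; rg not estimable",
      cross_intercept = fc$coef[1], n_snp = nrow(d), M = M),
      class = "ldsc_rg_fit"))
  }
  rg <- gcov / sqrt(h2a * h2b)
  B <- fa$n_blocks
  rg_j <- vapply(seq_len(B), function(k) {
    ha <- fa$jack[k, 2] * M / NAbar
    hb <- fb$jack[k, 2] * M / NBbar
    gc <- fc$jack[k, 2] * M / sqrt(NAbar * NBbar)
    if (ha <= 1e-8 || hb <= 1e-8) return(NA_real_)
    gc / sqrt(ha * hb)
  }, numeric(1))
  rg_j <- rg_j[is.finite(rg_j)]
  se <- if (length(rg_j) >= 2) jackknife_se(rg_j) else NA_real_
  structure(list(
    rg = rg, se_rg = se, p_rg0 = p_from_z(rg / se),
    h2 = c(h2a, h2b), gcov = gcov,
    cross_intercept = fc$coef[1],
    se_cross_intercept = jackknife_se(fc$jack[, 1]),
    intercepts = c(fa$coef[1], fb$coef[1]),
    n_snp = nrow(d), M = M, n_blocks = B), class = "ldsc_rg_fit")
}

#' @export
print.ldsc_rg_fit <- function(x, ...) {
  cat("cross-trait LD-score regression\n")
  if (is.na(x$rg)) {
    cat(sprintf("  rg not estimable: %s (h2 = %.4f / %.4f)\n", x$reason,
                x$h2[1], x$h2[2]))
  } else {
    cat(sprintf("  rg = %.4f (se %.4f), p = %.3g\n", x$rg, x$se_rg, x$p_rg0))
    cat(sprintf("  h2 = %.4f / %.4f; cross-trait intercept = %.4f\n",
                x$h2[1], x$h2[2], x$cross_intercept))
  }
  invisible(x)
}

#' Per-SNP SNP-by-environment interaction scan
#'
#' Fits, for every SNP, phenotype ~ covariates + E + dosage + dosage x E and
#' reports the Wald z of the interaction coefficient. The environment is
#' standardized internally; its main effect and the SNP main effect are
#' always included.
#'
#' @param panel a genotype_panel without missing dosages.
#' @param y phenotype vector.
#' @param E quantitative environment vector.
#' @param covariates optional covariate matrix.
#' @return summary-statistics data.frame (SNP, A1, A2, N, Z) for the
#'   interaction term.
#' @export
interaction_scan <- function(panel, y, E, covariates = NULL) {
  y <- as.numeric(y)
  E <- as.numeric(E)
  n <- length(y)
  stopifnot(length(E) == n, length(panel$sample_ids) == n)
  if (stats::sd(E) == 0) stop("environment is constant")
  if (anyNA(panel$dosage))
    stop("interaction_scan requires complete dosages")
  Ez <- as.numeric(scale(E))
  C <- cbind(intercept = rep(1, n), covariates, E = Ez)
  qC <- qr(C)
  yr <- qr.resid(qC, y)
  yry <- sum(yr^2)
  m <- nrow(panel$variants)
  df <- n - ncol(C) - 2
  z <- rep(NA_real_, m)
  chunk <- 2000L
  for (aa in seq(1, m, by = chunk)) {
    bb <- min(aa + chunk - 1L, m)
    G <- panel$dosage[, aa:bb, drop = FALSE]
    storage.mode(G) <- "double"
    GE <- G * Ez
    Gr <- qr.resid(qC, G)
    GEr <- qr.resid(qC, GE)
    a <- colSums(Gr^2)
    b <- colSums(Gr * GEr)
    cc <- colSums(GEr^2)
    u <- colSums(Gr * yr)
    v2 <- colSums(GEr * yr)
    det <- a * cc - b^2
    ok <- det > 1e-10
    b1 <- (cc * u - b * v2) / det
    b2 <- (a * v2 - b * u) / det
    rss <- pmax(yry - (b1 * u + b2 * v2), 0)
    s2 <- rss / df
    se2 <- s2 * a / det
    z[aa:bb] <- ifelse(ok, b2 / sqrt(se2), NA_real_)
  }
  data.frame(SNP = panel$variants$SNP, A1 = panel$variants$A1,
             A2 = panel$variants$A2, N = n, Z = z, stringsAsFactors = FALSE)
}

#' Estimate GxE interaction variance from interaction summary statistics
#'
#' Regression of the per-SNP interaction chi-square on LD scores under
#' E[chi2_j | l_j] = N sigma2_g1 / M * l_j + 1 + 2 (sigma2_g1 + sigma2_tau1):
#' the slope gives the GxE variance sigma2_g1 = b1 M / N and the intercept
#' the residual-heterogeneity (scale) variance
#' sigma2_tau1 = (b0 - 1) / 2 - sigma2_g1. SEs by block jackknife; a Wald
#' test of sigma2_g1 = 0 is reported. A negative sigma2_tau1 (intercept
#' below 1) is returned with a boundary flag.
#'
#' @param sumstats interaction summary statistics from [interaction_scan()].
#' @param ldscores data.frame from [compute_ld_scores()].
#' @param N sample size (default: mean of the N column).
#' @param M SNP count (default: regression SNPs).
#' @param n_blocks jackknife blocks.
#' @param chisq_max outlier cutoff; default max(80, 0.001 N).
#' @return object of class "gxesum_fit".
#' @export
gxesum_fit <- function(sumstats, ldscores, N = NULL, M = NULL,
                       n_blocks = 200, chisq_max = NULL) {
  d <- ldsc_merge(sumstats[!is.na(sumstats$Z), , drop = FALSE], ldscores)
  if (nrow(d) < 200) stop("fewer than 200 SNPs after merging")
  N <- N %||% mean(d$N)
  chisq <- d$Z^2
  chisq_max <- chisq_max %||% max(80, 0.001 * N)
  keep <- chisq <= chisq_max
  d <- d[keep, , drop = FALSE]; chisq <- chisq[keep]
  M <- M %||% nrow(d)
  w <- 1 / pmax(d$L2, 1)
  fit <- wls_blocks(d$L2, chisq, w, n_blocks)
  g1_of <- function(coef) coef[2] * M / N
  tau_of <- function(coef) (coef[1] - 1) / 2 - g1_of(coef)
  g1 <- g1_of(fit$coef)
  tau <- tau_of(fit$coef)
  g1_j <- apply(fit$jack, 1, g1_of)
  tau_j <- apply(fit$jack, 1, tau_of)
  structure(list(
    sigma2_g1 = g1, se_sigma2_g1 = jackknife_se(g1_j),
    sigma2_tau1 = tau, se_sigma2_tau1 = jackknife_se(tau_j),
    slope = fit$coef[2], intercept = fit$coef[1],
    p_g1 = p_from_z(g1 / jackknife_se(g1_j)),
    boundary = fit$coef[1] < 1,
    N = N, M = M, n_snp = nrow(d), n_blocks = fit$n_blocks),
    class = "gxesum_fit")
}

#' @export
print.gxesum_fit <- function(x, ...) {
  cat("GxE variance from interaction summary statistics\n")
  cat(sprintf("  sigma2_g1 = %.4f (se %.4f), p = %.3g\n", x$sigma2_g1,
              x$se_sigma2_g1, x$p_g1))
  cat(sprintf("  sigma2_tau1 = %.4f (se %.4f)%s\n", x$sigma2_tau1,
              x$se_sigma2_tau1,
              if (x$boundary) " [intercept < 1: boundary]" else ""))
  cat(sprintf("  %d SNPs (M = %d), N = %.0f\n", x$n_snp, x$M, x$N))
  invisible(x)
}
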