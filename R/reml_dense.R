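# General dense AI-REML engine for V = sum_k theta_k B_k.
# Used where no spectral shortcut applies (disjoint-strata bivariate models).

dense_eval <- function(theta, y, X, Blist) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(Blist)) V <- V + theta[k] * Blist[[k]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  RX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(RX)) return(NULL)
  W <- chol2inv(RX)
  Viy <- Vi %*% y
  Py <- as.numeric(Viy - ViX %*% (W %*% crossprod(X, Viy)))
  ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(RX))) + sum(y * Py))
  k <- length(Blist)
  trP <- numeric(k); yP <- numeric(k)
  U <- vector("list", k)
  for (i in seq_len(k)) {
    B <- Blist[[i]]
    trP[i] <- sum(Vi * B) - sum(W * crossprod(ViX, B %*% ViX))
    U[[i]] <- as.numeric(B %*% Py)
    yP[i] <- sum(Py * U[[i]])
  }
  Pu <- lapply(U, function(u)
    as.numeric(Vi %*% u - ViX %*% (W %*% crossprod(ViX, u))))
  AI <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k)
    AI[i, j] <- AI[j, i] <- 0.5 * sum(U[[i]] * Pu[[j]])
  list(ll = ll, score = -0.5 * (trP - yP), AI = AI)
}

reml_ai_dense <- function(y, X, Blist, start, lower = NULL, fixed = NULL,
                          max_iter = 100, tol = 1e-6) {
  theta <- start
  lower <- lower %||% rep(-Inf, length(theta))
  free <- setdiff(seq_along(theta), fixed)
  ev <- dense_eval(theta, y, X, Blist)
  if (is.null(ev)) stop("starting values give a non-PD covariance")
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    delta <- tryCatch(
      solve(ev$AI[free, free, drop = FALSE] + diag(1e-8, length(free)),
            ev$score[free]),
      error = function(e) ev$score[free] / length(y))
    theta_new <- theta
    theta_new[free] <- pmax(theta[free] + delta, lower[free])
    ev_new <- dense_eval(theta_new, y, X, Blist)
    halvings <- 0L
    while ((is.null(ev_new) || ev_new$ll < ev$ll - 1e-10) && halvings < 40L) {
      theta_new[free] <- pmax(theta[free] + (theta_new[free] - theta[free]) / 2,
                              lower[free])
      ev_new <- dense_eval(theta_new, y, X, Blist)
      halvings <- halvings + 1L
    }
    if (is.null(ev_new)) break
    dll <- ev_new$ll - ev$ll
    theta <- theta_new; ev <- ev_new
    if (abs(dll) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  V <- tryCatch(solve(ev$AI), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))
  list(theta = theta, vcov = V, loglik = ev$ll, iterations = iter,
       converged = converged)
}

#' Stratified (bivariate) GREML test for gene-environment interaction
#'
#' Splits the cohort by a two-level environment and treats the phenotype in
#' the two strata as two traits measured on disjoint samples. The bivariate
#' model has per-stratum genetic variances, a cross-stratum genetic covariance
#' structured by the between-stratum block of the GRM, and per-stratum
#' residual variances (no residual covariance: the samples are disjoint).
#' A genetic correlation significantly below 1 indicates that SNP effects are
#' modulated by the environment (GxE). Reports per-stratum heritabilities
#' (observed scale, plus liability scale for binary phenotypes), the
#' cross-stratum genetic correlation with SE, and Wald p-values for rg = 0 and
#' the GxE test rg = 1.
#'
#' @param y phenotype vector (binary 0/1 or quantitative).
#' @param env two-level environment labels aligned with \code{y}.
#' @param grm a [compute_grm()] aligned with \code{y}.
#' @param covariates optional covariate matrix (used in both strata).
#' @param min_cases minimum cases per stratum for a binary phenotype.
#' @return object of class "gxe_stratified_fit".
#' @export
gxe_stratified <- function(y, env, grm, covariates = NULL, min_cases = 50) {
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(length(env) == n, length(grm$sample_ids) == n)
  lev <- sort(unique(env[!is.na(env)]))
  if (length(lev) < 2) stop("environment is constant: need exactly two strata")
  if (length(lev) > 2) stop("stratified GxE requires exactly two strata")
  s1 <- which(env == lev[1]); s2 <- which(env == lev[2])
  binary <- all(y %in% c(0, 1))
  if (binary) {
    cases <- c(sum(y[s1]), sum(y[s2]))
    if (any(cases == 0)) stop("a stratum has zero cases")
    if (any(cases < min_cases))
      warning(sprintf("stratum case counts %s below %d; estimates unstable",
                      paste(cases, collapse = "/"), min_cases))
  }
  n1 <- length(s1); n2 <- length(s2)
  idx <- c(s1, s2)
  A <- grm$A[idx, idx]
  b1 <- seq_len(n1); b2 <- n1 + seq_len(n2)
  zmat <- function() matrix(0, n1 + n2, n1 + n2)
  Bg1 <- zmat(); Bg1[b1, b1] <- A[b1, b1]
  Bg2 <- zmat(); Bg2[b2, b2] <- A[b2, b2]
  Bg12 <- zmat(); Bg12[b1, b2] <- A[b1, b2]; Bg12[b2, b1] <- A[b2, b1]
  Be1 <- zmat(); diag(Be1)[b1] <- 1
  Be2 <- zmat(); diag(Be2)[b2] <- 1
  X1 <- cbind(intercept = rep(1, n1),
              if (!is.null(covariates)) covariates[s1, , drop = FALSE])
  X2 <- cbind(intercept = rep(1, n2),
              if (!is.null(covariates)) covariates[s2, , drop = FALSE])
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))
  yy <- y[idx]

  # per-stratum univariate fits supply starting values and h2 reports
  g1 <- subset_grm(grm, s1); g2 <- subset_grm(grm, s2)
  f1 <- reml_fit(y[s1], g1,
                 covariates = if (!is.null(covariates)) covariates[s1, , drop = FALSE])
  f2 <- reml_fit(y[s2], g2,
                 covariates = if (!is.null(covariates)) covariates[s2, , drop = FALSE])
  v1 <- stats::var(y[s1]); v2 <- stats::var(y[s2])
  start <- c(max(f1$sigma2_g, 1e-4 * v1), 0.5 * sqrt(f1$sigma2_g * f2$sigma2_g),
             max(f2$sigma2_g, 1e-4 * v2), f1$sigma2_e, f2$sigma2_e)
  lower <- c(1e-6 * v1, -Inf, 1e-6 * v2, 1e-6 * v1, 1e-6 * v2)
  fit <- reml_ai_dense(yy, X, list(Bg1, Bg12, Bg2, Be1, Be2), start, lower)
  rgse <- rg_from_theta(fit$theta, fit$vcov)
  rg_raw <- rgse$rg
  rg <- rg_raw; clamped <- FALSE
  if (!is.na(rg) && abs(rg) > 1) { rg <- sign(rg); clamped <- TRUE }
  h2 <- c(fit$theta[1] / (fit$theta[1] + fit$theta[4]),
          fit$theta[3] / (fit$theta[3] + fit$theta[5]))
  out <- list(strata = as.character(lev), n = c(n1, n2),
              h2_obs = h2,
              se_h2_obs = c(f1$se_h2, f2$se_h2),
              rg = rg, rg_raw = rg_raw, se_rg = rgse$se,
              p_rg0 = p_from_z(rg_raw / rgse$se),
              p_rg1 = p_from_z((rg_raw - 1) / rgse$se),
              theta = fit$theta, vcov = fit$vcov, loglik = fit$loglik,
              converged = fit$converged, clamped = clamped,
              univariate = list(f1, f2))
  if (binary) {
    P1 <- mean(y[s1]); P2 <- mean(y[s2])
    out$h2_liability <- c(h2[1] * liability_multiplier(P1),
                          h2[2] * liability_multiplier(P2))
    out$prevalence <- c(P1, P2)
  }
  structure(out, class = "gxe_stratified_fit")
}

#' @export
print.gxe_stratified_fit <- function(x, ...) {
  cat("stratified GREML gene-environment interaction\n")
  for (i in 1:2) {
    cat(sprintf("  stratum %s (n = %d): h2_obs = %.4f", x$strata[i], x$n[i],
                x$h2_obs[i]))
    if (!is.null(x$h2_liability))
      cat(sprintf(", h2_liability = %.4f", x$h2_liability[i]))
    cat("\n")
  }
  cat(sprintf("  rg = %.4f (se %.4f); p(rg = 1) = %.3g; p(rg = 0) = %.3g\n",
              x$rg, x$se_rg, x$p_rg1, x$p_rg0))
  invisible(x)
}
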