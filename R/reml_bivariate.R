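# Bivariate GREML on a shared sample set.
#
# theta = (g11, g12, g22, e11, e12, e22); in the eigenbasis of the GRM the
# covariance is block diagonal with one 2x2 block per eigenvalue, so every
# iteration is O(n p^2). Used for pairs of traits measured on the same
# individuals; disjoint-strata designs go through the dense engine.

bv_structures <- function(d) {
  n <- length(d)
  one <- rep(1, n)
  # per-block symmetric 2x2 structure (alpha, beta, gamma) for each component
  list(g11 = list(a = d,  b = 0 * d, c = 0 * d),
       g12 = list(a = 0 * d, b = d,  c = 0 * d),
       g22 = list(a = 0 * d, b = 0 * d, c = d),
       e11 = list(a = one, b = 0 * one, c = 0 * one),
       e12 = list(a = 0 * one, b = one, c = 0 * one),
       e22 = list(a = 0 * one, b = 0 * one, c = one))
}

bv_eval <- function(theta, d, Y, X1t, X2t) {
  a <- theta[1] * d + theta[4]
  b <- theta[2] * d + theta[5]
  cc <- theta[3] * d + theta[6]
  det <- a * cc - b^2
  if (any(det <= 0) || any(a <= 0) || any(cc <= 0)) return(NULL)
  ia <- cc / det; ib <- -b / det; ic <- a / det
  p1 <- ncol(X1t); p2 <- ncol(X2t)
  XtVX <- rbind(
    cbind(crossprod(X1t, X1t * ia), crossprod(X1t, X2t * ib)),
    cbind(crossprod(X2t, X1t * ib), crossprod(X2t, X2t * ic)))
  R <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Winv <- chol2inv(R)
  y1 <- Y[, 1]; y2 <- Y[, 2]
  Vz <- function(z1, z2) cbind(ia * z1 + ib * z2, ib * z1 + ic * z2)
  Pz <- function(z1, z2) {
    vz <- Vz(z1, z2)
    rhs <- c(crossprod(X1t, vz[, 1]), crossprod(X2t, vz[, 2]))
    beta <- Winv %*% rhs
    xb1 <- as.numeric(X1t %*% beta[seq_len(p1)])
    xb2 <- as.numeric(X2t %*% beta[p1 + seq_len(p2)])
    vz - Vz(xb1, xb2)
  }
  Py <- Pz(y1, y2)
  ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(R))) +
                  sum(y1 * Py[, 1] + y2 * Py[, 2]))

  st <- bv_structures(d)
  k <- length(st)
  score <- numeric(k); yP <- numeric(k); trP <- numeric(k)
  U <- vector("list", k)
  for (i in seq_len(k)) {
    s <- st[[i]]
    # tr(V^-1 B) over blocks
    trV <- sum(ia * s$a) + 2 * sum(ib * s$b) + sum(ic * s$c)
    # weights of V^-1 B V^-1 per block
    w11 <- ia^2 * s$a + 2 * ia * ib * s$b + ib^2 * s$c
    w12 <- ia * ib * s$a + (ia * ic + ib^2) * s$b + ib * ic * s$c
    w22 <- ib^2 * s$a + 2 * ib * ic * s$b + ic^2 * s$c
    Nk <- rbind(
      cbind(crossprod(X1t, X1t * w11), crossprod(X1t, X2t * w12)),
      cbind(crossprod(X2t, X1t * w12), crossprod(X2t, X2t * w22)))
    trP[i] <- trV - sum(Winv * Nk)
    u1 <- s$a * Py[, 1] + s$b * Py[, 2]
    u2 <- s$b * Py[, 1] + s$c * Py[, 2]
    yP[i] <- sum(Py[, 1] * u1 + Py[, 2] * u2)
    U[[i]] <- cbind(u1, u2)
  }
  score <- -0.5 * (trP - yP)
  PU <- lapply(U, function(u) Pz(u[, 1], u[, 2]))
  AI <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    AI[i, j] <- AI[j, i] <-
      0.5 * sum(U[[i]][, 1] * PU[[j]][, 1] + U[[i]][, 2] * PU[[j]][, 2])
  }
  list(ll = ll, score = score, AI = AI, yP = yP, tr = trP)
}

bv_fit_engine <- function(theta, d, Y, X1t, X2t, max_iter = 100, tol = 1e-6,
                          fixed = NULL) {
  free <- setdiff(seq_along(theta), fixed)
  ev <- bv_eval(theta, d, Y, X1t, X2t)
  if (is.null(ev)) stop("starting values give a non-PD covariance")
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    delta <- tryCatch(
      solve(ev$AI[free, free, drop = FALSE] +
              diag(1e-8, length(free)), ev$score[free]),
      error = function(e) NULL)
    if (is.null(delta)) delta <- ev$score[free] / nrow(Y)
    theta_new <- theta
    theta_new[free] <- theta[free] + delta
    ev_new <- bv_eval(theta_new, d, Y, X1t, X2t)
    halvings <- 0L
    while ((is.null(ev_new) || ev_new$ll < ev$ll - 1e-10) && halvings < 40L) {
      theta_new[free] <- theta[free] + (theta_new[free] - theta[free]) / 2
      ev_new <- bv_eval(theta_new, d, Y, X1t, X2t)
      halvings <- halvings + 1L
    }
    if (is.null(ev_new)) break
    dll <- ev_new$ll - ev$ll
    theta <- theta_new; ev <- ev_new
    if (abs(dll) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(theta = theta, ev = ev, iterations = iter, converged = converged,
       free = free)
}

rg_from_theta <- function(theta, V, ig1 = 1, ig12 = 2, ig2 = 3) {
  g1 <- theta[ig1]; g12 <- theta[ig12]; g2 <- theta[ig2]
  if (g1 <= 0 || g2 <= 0) return(list(rg = NA_real_, se = NA_real_))
  rg <- g12 / sqrt(g1 * g2)
  gr <- numeric(length(theta))
  gr[ig1] <- -rg / (2 * g1)
  gr[ig12] <- 1 / sqrt(g1 * g2)
  gr[ig2] <- -rg / (2 * g2)
  se <- sqrt(max(0, crossprod(gr, V %*% gr)))
  list(rg = rg, se = se)
}

#' Bivariate GREML genetic correlation between two traits
#'
#' Fits the bivariate linear mixed model with genetic covariance structured by
#' the GRM and unstructured residual covariance, by average-information REML
#' in the eigenbasis of the GRM. Both traits must be measured on the same
#' samples (disjoint-strata designs are handled by [gxe_stratified()]).
#' Reports the genetic correlation rg = sigma_g12 / sqrt(sigma2_g1 sigma2_g2)
#' with a delta-method SE, Wald tests of rg = 0 and rg = 1, and optionally a
#' likelihood-ratio test against the model with both covariance parameters
#' (genetic and residual) fixed at zero, referred to chi-square with 2 df.
#'
#' @param y1,y2 trait vectors on the same samples (aligned with the GRM).
#' @param grm a [compute_grm()] object.
#' @param covariates optional covariate matrix (shared by both traits).
#' @param lrt also compute the 2-df likelihood-ratio test of no covariance.
#' @param eig optional precomputed eigendecomposition of \code{grm$A}.
#' @param max_iter,tol REML iteration controls.
#' @return object of class "rg_estimate": components \code{rg}, \code{se_rg},
#'   \code{p_rg0}, \code{p_rg1}, per-trait \code{h2}, variance components
#'   \code{theta}, \code{clamped}, and (optionally) \code{lrt}.
#' @export
bivariate_reml <- function(y1, y2, grm, covariates = NULL, lrt = FALSE,
                           eig = NULL, max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(grm, "grm"))
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  n <- length(grm$sample_ids)
  stopifnot(length(y1) == n, length(y2) == n)
  X <- cbind(intercept = rep(1, n), covariates)
  eig <- eig %||% eigen(grm$A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  Y <- crossprod(U, cbind(y1, y2))
  Xt <- crossprod(U, X)

  f1 <- reml_fit(y1, grm, covariates, eig = eig)
  f2 <- reml_fit(y2, grm, covariates, eig = eig)
  if (!is.na(f1$h2_obs) && f1$sigma2_g <= 1.5e-6 * stats::var(y1) ||
      !is.na(f2$h2_obs) && f2$sigma2_g <= 1.5e-6 * stats::var(y2)) {
    return(structure(list(
      rg = NA_real_, se_rg = NA_real_, p_rg0 = NA_real_, p_rg1 = NA_real_,
      h2 = c(f1$h2_obs, f2$h2_obs), theta = NULL, converged = FALSE,
      reason = "heritability at the boundary floor; rg undefined",
      univariate = list(f1, f2)), class = "rg_estimate"))
  }
  r0 <- stats::cor(y1, y2)
  if (abs(r0) > 1 - 1e-12) {
    # degenerate pair: the likelihood supremum sits on the PD boundary
    return(structure(list(
      rg = sign(r0), rg_raw = sign(r0), se_rg = 0, p_rg0 = 0, p_rg1 = NA_real_,
      h2 = c(f1$h2_obs, f2$h2_obs), sigma_g12 = sign(r0) * f1$sigma2_g,
      theta = NULL, converged = TRUE, clamped = FALSE, test = "Wald", n = n,
      reason = "traits perfectly correlated; covariance at the PD boundary",
      univariate = list(f1, f2)), class = "rg_estimate"))
  }
  theta0 <- c(f1$sigma2_g, 0.5 * r0 * sqrt(f1$sigma2_g * f2$sigma2_g),
              f2$sigma2_g, f1$sigma2_e, 0.5 * r0 * sqrt(f1$sigma2_e * f2$sigma2_e),
              f2$sigma2_e)
  fit <- bv_fit_engine(theta0, d, Y, Xt, Xt, max_iter = max_iter, tol = tol)
  V <- tryCatch(solve(fit$ev$AI), error = function(e) matrix(NA_real_, 6, 6))
  rgse <- rg_from_theta(fit$theta, V)
  rg_raw <- rgse$rg
  clamped <- FALSE
  rg <- rg_raw
  if (!is.na(rg) && abs(rg) > 1) { rg <- sign(rg); clamped <- TRUE }
  h2 <- c(fit$theta[1] / (fit$theta[1] + fit$theta[4]),
          fit$theta[3] / (fit$theta[3] + fit$theta[6]))
  out <- structure(list(
    rg = rg, rg_raw = rg_raw, se_rg = rgse$se,
    reason = if (is.na(rg_raw))
      "genetic variance non-positive at the optimum; rg not estimable",
    p_rg0 = p_from_z(rg_raw / rgse$se),
    p_rg1 = p_from_z((rg_raw - 1) / rgse$se),
    h2 = h2, sigma_g12 = fit$theta[2], theta = fit$theta, vcov = V,
    loglik = fit$ev$ll, iterations = fit$iterations,
    converged = fit$converged, clamped = clamped, test = "Wald", n = n,
    univariate = list(f1, f2)), class = "rg_estimate")
  if (lrt) {
    ll0 <- bv_fit_engine(replace(theta0, c(2, 5), 0), d, Y, Xt, Xt,
                         fixed = c(2L, 5L), max_iter = max_iter,
                         tol = tol)$ev$ll
    stat <- max(0, 2 * (fit$ev$ll - ll0))
    out$lrt <- list(stat = stat, df = 2, p = stats::pchisq(stat, 2,
                                                           lower.tail = FALSE))
  }
  out
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat("bivariate GREML genetic correlation\n")
  if (is.na(x$rg)) {
    cat(sprintf("  rg not estimable: %s\n", x$reason %||% "unknown"))
  } else {
    cat(sprintf("  rg = %.4f (se %.4f)%s\n", x$rg, x$se_rg,
                if (isTRUE(x$clamped)) " [clamped to [-1, 1]]" else ""))
    cat(sprintf("  p(rg = 0) = %.3g; p(rg = 1) = %.3g [%s]\n",
                x$p_rg0, x$p_rg1, x$test))
    cat(sprintf("  h2 = %.4f / %.4f (observed scale)\n", x$h2[1], x$h2[2]))
    if (!is.null(x$lrt))
      cat(sprintf("  LRT (no covariance, %d df): stat = %.3f, p = %.3g\n",
                  x$lrt$df, x$lrt$stat, x$lrt$p))
  }
  invisible(x)
}
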