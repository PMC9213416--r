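# Univariate GREML: y = Xb + a + e, a ~ N(0, A*sg2), e ~ N(0, I*se2).
# After one spectral decomposition A = U D U' the rotated covariance is
# diagonal, so every REML iteration costs O(n p^2) instead of O(n^3).

uv_eval <- function(theta, d, yt, Xt) {
  v <- theta[1] * d + theta[2]
  if (any(v <= 0)) return(NULL)
  w <- 1 / v
  Xw <- Xt * w
  XtVX <- crossprod(Xt, Xw)
  R <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Winv <- chol2inv(R)
  Py <- as.numeric(yt * w - Xw %*% (Winv %*% crossprod(Xw, yt)))
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(R))) + sum(yt * Py))
  Pz <- function(z) {
    zw <- z * w
    as.numeric(zw - Xw %*% (Winv %*% crossprod(Xt, zw)))
  }
  tr_g <- sum(d * w) - sum(Winv * crossprod(Xt, Xt * (d * w^2)))
  tr_e <- sum(w) - sum(Winv * crossprod(Xt, Xt * w^2))
  yPgPy <- sum(d * Py^2)
  yPePy <- sum(Py^2)
  u_g <- d * Py
  Pu_g <- Pz(u_g)
  Pu_e <- Pz(Py)
  AI <- 0.5 * matrix(c(sum(u_g * Pu_g), sum(u_g * Pu_e),
                       sum(u_g * Pu_e), sum(Py * Pu_e)), 2, 2)
  list(ll = ll, Py = Py, score = -0.5 * c(tr_g - yPgPy, tr_e - yPePy),
       AI = AI, yP = c(yPgPy, yPePy), tr = c(tr_g, tr_e))
}

#' REML log-likelihood of the single-GRM linear mixed model
#'
#' Evaluates the restricted log-likelihood (up to an additive constant) of
#' y = Xb + a + e with var(a) = A*sigma2_g and var(e) = I*sigma2_e. Used by
#' grid-search cross-checks and profiling.
#'
#' @param y response vector.
#' @param grm a [compute_grm()] object (or any "grm").
#' @param sigma2_g,sigma2_e variance components (must give a PD covariance).
#' @param covariates optional numeric matrix of fixed-effect covariates
#'   (an intercept is always included).
#' @param eig optional precomputed \code{eigen(grm$A, symmetric = TRUE)}.
#' @return the restricted log-likelihood.
#' @export
reml_loglik <- function(y, grm, sigma2_g, sigma2_e, covariates = NULL,
                        eig = NULL) {
  eig <- eig %||% eigen(grm$A, symmetric = TRUE)
  X <- cbind(intercept = rep(1, length(y)), covariates)
  d <- pmax(eig$values, 0)
  ev <- uv_eval(c(sigma2_g, sigma2_e), d, crossprod(eig$vectors, y),
                crossprod(eig$vectors, X))
  if (is.null(ev)) stop("covariance not positive definite at these components")
  ev$ll
}

#' Fit the univariate GREML model by AI-REML
#'
#' Restricted maximum likelihood for the single-GRM linear mixed model, run as
#' two EM warm-up iterations followed by average-information updates with
#' step-halving, declared converged when the log-likelihood changes by less
#' than \code{tol} (default 1e-6, at most \code{max_iter} iterations).
#' Variance components are floored at \code{1e-6 * var(y)} to keep the
#' covariance positive definite; boundary hits are flagged. Standard errors
#' come from the inverse average-information matrix and the heritability SE
#' from the delta method. Binary 0/1 phenotypes are analysed on the observed
#' scale (linear mixed model) and can be converted afterwards with
#' [observed_to_liability()].
#'
#' @param y response vector (quantitative trait or 0/1 disease status).
#' @param grm a [compute_grm()] object aligned with \code{y}.
#' @param covariates optional numeric matrix of covariates.
#' @param max_iter maximum REML iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param eig optional precomputed eigendecomposition of \code{grm$A}.
#' @return object of class "heritability_estimate" with components
#'   \code{sigma2_g}, \code{sigma2_e} (with SEs), \code{h2_obs},
#'   \code{se_h2}, \code{p_h2}, \code{loglik}, \code{iterations},
#'   \code{converged}, \code{n}, \code{flags} and \code{vcov}.
#' @export
reml_fit <- function(y, grm, covariates = NULL, max_iter = 100, tol = 1e-6,
                     eig = NULL) {
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 50) stop("GREML requires n >= 50")
  if (n != length(grm$sample_ids)) stop("y and GRM are not aligned")
  X <- cbind(intercept = rep(1, n), covariates)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effects design")
  eig <- eig %||% eigen(grm$A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  vary <- stats::var(y)
  floor_v <- 1e-6 * vary
  flags <- character(0)

  if (stats::sd(d) < 1e-8) {
    # GRM proportional to the identity: sg2 and se2 identified only in sum
    res <- stats::lm.fit(X, y)$residuals
    tot <- sum(res^2) / (n - ncol(X))
    return(structure(list(
      sigma2_g = NA_real_, se_g = NA_real_, sigma2_e = NA_real_,
      se_e = NA_real_, sigma2_total = tot, h2_obs = NA_real_,
      se_h2 = NA_real_, p_h2 = NA_real_, loglik = NA_real_, iterations = 0L,
      converged = TRUE, n = n, flags = "non-identified split", vcov = NULL),
      class = "heritability_estimate"))
  }

  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  theta <- c(vary / 2, vary / 2)
  ev <- uv_eval(theta, d, yt, Xt)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    if (iter <= 2L) {                      # EM warm-up
      theta_new <- theta + theta^2 * (ev$yP - ev$tr) / n
    } else {                               # AI update with step-halving
      delta <- tryCatch(solve(ev$AI, ev$score), error = function(e) NULL)
      if (is.null(delta)) delta <- ev$score / n
      theta_new <- theta + delta
    }
    theta_new <- pmax(theta_new, floor_v)
    ev_new <- uv_eval(theta_new, d, yt, Xt)
    halvings <- 0L
    while ((is.null(ev_new) || ev_new$ll < ev$ll - 1e-10) && halvings < 30L) {
      theta_new <- pmax(theta + (theta_new - theta) / 2, floor_v)
      ev_new <- uv_eval(theta_new, d, yt, Xt)
      halvings <- halvings + 1L
    }
    if (is.null(ev_new)) {
      flags <- c(flags, "step failure")
      break
    }
    dll <- ev_new$ll - ev$ll
    theta <- theta_new
    ev <- ev_new
    if (iter > 2L && abs(dll) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) flags <- c(flags, "not converged; last iterate returned")
  if (any(theta <= floor_v * (1 + 1e-8)))
    flags <- c(flags, "component at boundary floor")

  V <- tryCatch(solve(ev$AI), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sum(theta)
  h2 <- theta[1] / tot
  gr <- c(theta[2], -theta[1]) / tot^2
  se_h2 <- sqrt(max(0, crossprod(gr, V %*% gr)))
  structure(list(
    sigma2_g = theta[1], se_g = sqrt(abs(V[1, 1])), sigma2_e = theta[2],
    se_e = sqrt(abs(V[2, 2])), sigma2_total = tot, h2_obs = h2,
    se_h2 = se_h2, p_h2 = p_from_z(h2 / se_h2), loglik = ev$ll,
    iterations = iter, converged = converged, n = n,
    flags = if (length(flags)) flags else "ok", vcov = V),
    class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat("GREML heritability estimate\n")
  if (!is.na(x$h2_obs)) {
    cat(sprintf("  sigma2_g = %.4f (%.4f), sigma2_e = %.4f (%.4f)\n",
                x$sigma2_g, x$se_g, x$sigma2_e, x$se_e))
    cat(sprintf("  h2 (observed scale) = %.4f (se %.4f), p = %.3g\n",
                x$h2_obs, x$se_h2, x$p_h2))
    if (!is.null(x$h2_liability))
      cat(sprintf("  h2 (liability scale) = %.4f (se %.4f), K = %.4f\n",
                  x$h2_liability, x$se_h2_liability, x$K))
  } else {
    cat(sprintf("  total variance = %.4f [%s]\n", x$sigma2_total,
                paste(x$flags, collapse = "; ")))
  }
  cat(sprintf("  logL = %.3f after %d iterations (converged: %s); n = %d\n",
              x$loglik, x$iterations, x$converged, x$n))
  invisible(x)
}

#' Liability-scale multiplier for observed-scale case-control heritability
#'
#' The transformation factor K^2 (1-K)^2 / (P (1-P) z^2), where K is the
#' population prevalence, P the sample case proportion and z the standard
#' normal density at the liability threshold qnorm(1 - K). When K = P this
#' reduces to K (1-K) / z^2.
#'
#' @param K population lifetime prevalence in (0, 1).
#' @param P sample case proportion in (0, 1); defaults to K.
#' @return the multiplicative factor applied to observed-scale h2 and its SE.
#' @export
liability_multiplier <- function(K, P = K) {
  stop_if_not_scalar_prob(K, "K")
  stop_if_not_scalar_prob(P, "P")
  z <- stats::dnorm(stats::qnorm(1 - K))
  K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' Convert an observed-scale heritability estimate to the liability scale
#'
#' Applies the threshold-model transformation of the observed-scale (0/1)
#' heritability to the liability scale; the SE is multiplied by the same
#' factor. The usual convention when the sample is population-representative
#' is to set the population prevalence equal to the sample case proportion
#' (K = P).
#'
#' @param est a "heritability_estimate" from [reml_fit()] (or a bare numeric
#'   h2 with \code{se} supplied).
#' @param K population lifetime prevalence.
#' @param P sample case proportion (defaults to K).
#' @param se SE of h2 when \code{est} is numeric.
#' @return for an estimate object: the object augmented with
#'   \code{h2_liability}, \code{se_h2_liability}, \code{K}, \code{P} and
#'   \code{z}; for a numeric: a list with the same fields.
#' @export
observed_to_liability <- function(est, K, P = K, se = NULL) {
  mult <- liability_multiplier(K, P)
  z <- stats::dnorm(stats::qnorm(1 - K))
  if (inherits(est, "heritability_estimate")) {
    est$h2_liability <- est$h2_obs * mult
    est$se_h2_liability <- est$se_h2 * mult
    est$K <- K; est$P <- P; est$z <- z
    est
  } else {
    list(h2_liability = est * mult, se_h2_liability = (se %||% NA_real_) * mult,
         K = K, P = P, z = z, multiplier = mult)
  }
}
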