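#' Meta-analyse estimates from independent sample splits
#'
#' Point estimates are pooled by fixed-effect inverse-variance weighting
#' (Fisher's method cannot pool estimates); p-values are combined with
#' Fisher's statistic X = -2 * sum(log p_i), referred to chi-square with
#' 2k degrees of freedom.
#'
#' @param estimates numeric vector of per-split estimates.
#' @param se numeric vector of their standard errors.
#' @param p numeric vector of their p-values.
#' @return object of class "meta_estimate": \code{estimate}, \code{se}
#'   (inverse-variance pooled), \code{fisher_stat}, \code{df}, \code{p}
#'   (Fisher combined) and \code{k}.
#' @export
split_meta <- function(estimates, se, p) {
  k <- length(estimates)
  stopifnot(k >= 2, length(se) == k, length(p) == k)
  if (any(!is.finite(se)) || any(se <= 0)) stop("non-finite or zero SEs")
  w <- 1 / se^2
  pooled <- sum(w * estimates) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  if (any(p == 0)) {
    warning("a member p-value is exactly 0; combined p reported as 0")
    X <- Inf; p_comb <- 0
  } else {
    X <- -2 * sum(log(p))
    p_comb <- stats::pchisq(X, df = 2 * k, lower.tail = FALSE)
  }
  structure(list(estimate = pooled, se = pooled_se, fisher_stat = X,
                 df = 2 * k, p = p_comb, k = k), class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("meta-analysis of %d splits: %.4f (se %.4f)\n", x$k,
              x$estimate, x$se))
  cat(sprintf("  Fisher's statistic %.4f on %d df, combined p = %.4g\n",
              x$fisher_stat, x$df, x$p))
  invisible(x)
}
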