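#' Pearson phenotypic correlation with a Fisher-z significance test
#'
#' Pairwise-complete Pearson correlation; the two-tailed p-value uses the
#' normal distribution of the Fisher-transformed coefficient,
#' p = 2 Phi(-|atanh(r)| sqrt(n - 3)). Binary traits go through the same
#' machinery (point-biserial correlation). The SE is reported on both scales:
#' 1/sqrt(n - 3) for z and (1 - r^2)/sqrt(n - 3) on the r scale.
#'
#' @param x,y paired observations (NAs dropped pairwise).
#' @return object of class "pheno_correlation": r, se_r, se_z, p, n.
#' @export
phenotypic_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) stop("need at least 4 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
    z <- sign(r) * Inf
  } else {
    z <- atanh(r)
    p <- p_from_z(z * sqrt(n - 3))
  }
  structure(list(r = r, se_r = (1 - r^2) / sqrt(n - 3),
                 se_z = 1 / sqrt(n - 3), z = z, p = p, n = n),
            class = "pheno_correlation")
}

#' @export
print.pheno_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (se %.4f), p = %.3g, n = %d\n",
              x$r, x$se_r, x$p, x$n))
  invisible(x)
}

#' Calculated free oestradiol from total oestradiol, SHBG and albumin
#'
#' Literal evaluation of
#' cFO = (E2 - N_total) / (N_SHBG - (E2 + N_E2)) with
#' N_E2 = 0.64e9 * albumin + 1, N_SHBG = 5.55e4 * SHBG and
#' N_total = N_SHBG + N_E2. Units pass through unconverted and all
#' intermediates are retained. A vanishing denominator is an error, never an
#' infinity. See also [free_estradiol_mass_action()] for a conventional
#' mass-action alternative.
#'
#' @param E2 serum oestradiol level(s).
#' @param SHBG sex-hormone-binding-globulin concentration(s).
#' @param albumin albumin concentration(s).
#' @return data.frame with E2, SHBG, albumin, N_E2, N_SHBG, N_total, cFO.
#' @export
free_estradiol <- function(E2, SHBG, albumin) {
  if (any(E2 < 0, na.rm = TRUE) || any(SHBG < 0, na.rm = TRUE) ||
      any(albumin < 0, na.rm = TRUE))
    stop("inputs must be non-negative")
  k <- max(length(E2), length(SHBG), length(albumin))
  E2 <- rep_len(E2, k); SHBG <- rep_len(SHBG, k); albumin <- rep_len(albumin, k)
  N_E2 <- 0.64e9 * albumin + 1
  N_SHBG <- 5.55e4 * SHBG
  N_total <- N_SHBG + N_E2
  den <- N_SHBG - (E2 + N_E2)
  if (any(den == 0, na.rm = TRUE))
    stop("free-oestradiol denominator vanishes for at least one record")
  data.frame(E2 = E2, SHBG = SHBG, albumin = albumin, N_E2 = N_E2,
             N_SHBG = N_SHBG, N_total = N_total,
             cFO = (E2 - N_total) / den)
}

#' Free oestradiol by the standard mass-action quadratic
#'
#' Conventional free-hormone calculation assuming 1:1 binding of oestradiol
#' to SHBG (association constant \code{k_shbg}, L/mol) and linear,
#' non-saturable binding to albumin: the free concentration F solves the
#' standard quadratic a F^2 + b F - E2 = 0 with a = k_shbg (1 + k_alb Alb)
#' and b = 1 + k_alb Alb + k_shbg (SHBG - E2); the positive root is
#' returned. The default albumin term (0.634 per g/L) is the albumin
#' association constant divided by its molar mass, so albumin can be given
#' in conventional g/L units. Provided for comparison; the literal published
#' formula ([free_estradiol()]) is the default elsewhere in the package.
#'
#' @param E2 total oestradiol (mol/L).
#' @param SHBG SHBG concentration (mol/L).
#' @param albumin albumin concentration (g/L).
#' @param k_shbg SHBG association constant (L/mol).
#' @param k_alb albumin association term per g/L.
#' @return vector of free oestradiol concentrations.
#' @export
free_estradiol_mass_action <- function(E2, SHBG, albumin,
                                       k_shbg = 3.14e8, k_alb = 0.634) {
  a <- k_shbg * (1 + k_alb * albumin)
  b <- 1 + k_alb * albumin + k_shbg * (SHBG - E2)
  (-b + sqrt(b^2 + 4 * a * E2)) / (2 * a)
}

#' Leave-one-out groupings of disease subtypes
#'
#' For each subtype, builds the grouped phenotype that excludes it: the union
#' of the remaining subtype indicators (missing counts as unaffected when at
#' least one subtype is observed). Exactly one fold per subtype.
#'
#' @param statuses data.frame or matrix of 0/1/NA subtype indicators, one
#'   column per subtype.
#' @return list of folds; each fold has \code{held_out}, \code{included} and
#'   \code{grouped} (0/1 vector).
#' @export
loo_groupings <- function(statuses) {
  statuses <- as.data.frame(statuses)
  subtypes <- names(statuses)
  if (length(subtypes) < 2) stop("need at least 2 subtypes")
  if (anyDuplicated(subtypes)) stop("duplicate subtype names")
  lapply(subtypes, function(s) {
    rest <- statuses[, setdiff(subtypes, s), drop = FALSE]
    grouped <- as.integer(rowSums(rest == 1, na.rm = TRUE) > 0)
    list(held_out = s, included = setdiff(subtypes, s), grouped = grouped)
  })
}

#' Leave-one-out genetic-correlation grid
#'
#' For every subtype, runs a GWAS of the subtype and of the grouped phenotype
#' excluding it, then estimates their genetic correlation by cross-trait
#' LD-score regression ([ldsc_rg()]). Cells where either trait's heritability
#' is not estimable are reported with the failure reason rather than a value.
#'
#' @param panel a genotype_panel.
#' @param statuses data.frame of 0/1/NA subtype indicators.
#' @param ldscores LD scores for the panel.
#' @param covariates optional covariate matrix for the scans.
#' @return data.frame with held_out, rg, se, n_cases_subtype and reason.
#' @export
loo_rg_grid <- function(panel, statuses, ldscores, covariates = NULL) {
  folds <- loo_groupings(statuses)
  rows <- lapply(folds, function(f) {
    y_sub <- statuses[[f$held_out]]
    y_sub0 <- ifelse(is.na(y_sub), 0L, y_sub)  # excluded sex treated as control
    n_cases <- sum(y_sub == 1, na.rm = TRUE)
    res <- tryCatch({
      sa <- association_scan(panel, y_sub0, covariates)
      sb <- association_scan(panel, f$grouped, covariates)
      fit <- ldsc_rg(assoc_to_sumstats(sa), assoc_to_sumstats(sb), ldscores)
      if (is.na(fit$rg)) list(rg = NA_real_, se = NA_real_, reason = fit$reason)
      else list(rg = fit$rg, se = fit$se_rg, reason = "")
    }, error = function(e) list(rg = NA_real_, se = NA_real_,
                                reason = conditionMessage(e)))
    data.frame(held_out = f$held_out, rg = res$rg, se = res$se,
               n_cases_subtype = n_cases, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
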