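#' Default cancer-subtype specification for the reference synthetic cohort
#'
#' Five binary disease subtypes mimic the composition of a grouped
#' hormone-sensitive cancer phenotype: three female-restricted subtypes
#' (breast-, uterine- and ovarian-like), one male-restricted (prostate-like)
#' and one affecting both sexes (thyroid-like). Prevalences are within-eligible-
#' sex lifetime risks chosen so the grouped sample proportion lands near 6%,
#' the reference scenario for the grouped phenotype. Each subtype has a
#' liability-scale heritability and a loading on a single shared polygenic
#' factor, so pairwise genetic correlations between subtypes t and t' equal
#' c_t * c_t'.
#'
#' @return data.frame with columns name, sex, prevalence, h2, shared_loading,
#'   n_causal_shared, n_causal_specific.
#' @export
default_subtypes <- function() {
  data.frame(
    name = c("breast_like", "prostate_like", "uterine_like", "ovarian_like",
             "thyroid_like"),
    sex = c("female", "male", "female", "female", "both"),
    prevalence = c(0.045, 0.050, 0.012, 0.008, 0.005),
    h2 = c(0.10, 0.12, 0.08, 0.08, 0.08),
    shared_loading = c(0.70, 0.70, 0.60, 0.60, 0.50),
    n_causal_shared = NA_integer_,   # filled from the panel size by sim_config()
    n_causal_specific = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Default quantitative non-cancer trait specification
#'
#' Endocrine/anthropometric-style quantitative traits with a target
#' heritability and a genetic correlation with the grouped disease liability.
#'
#' @return data.frame with columns name, h2, rg.
#' @export
default_traits <- function() {
  data.frame(
    name = c("igf1_like", "oestradiol_like", "shbg_like", "albumin_like",
             "height_like"),
    h2 = c(0.25, 0.15, 0.20, 0.15, 0.50),
    rg = c(0.25, -0.20, -0.10, 0.00, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration for the synthetic cohort generator
#'
#' The configuration fixes everything the generator needs: panel dimensions,
#' allele-frequency spectrum, block-LD structure, the liability-threshold
#' disease model (subtype prevalences, heritabilities, shared-factor loadings,
#' causal-set sizes), correlated quantitative traits, gene-environment
#' structure and covariate effects on liability.
#'
#' @param n_samples number of individuals.
#' @param n_variants number of SNPs.
#' @param master_seed integer master seed; every stage derives a named
#'   substream from it via [substream_seed()].
#' @param maf_range length-2 numeric, minor-allele-frequency range in (0, 0.5].
#' @param ld_block_length SNPs per LD block.
#' @param ld_rho within-block latent AR(1) correlation in [0, 1).
#' @param subtype_specs data.frame as [default_subtypes()].
#' @param trait_specs data.frame as [default_traits()].
#' @param gxe_spec list with sigma2_g0, sigma2_g1, sigma2_tau1 (variance
#'   fractions) and environment ("quantitative" or "binary"), or NULL to skip.
#' @param covariate_spec named list of liability variance fractions for the
#'   age/sex/centre/batch covariates.
#' @param missing_rate per-entry genotype missingness rate.
#' @param incident_rate probability a case is flagged incident (Bernoulli
#'   thinning; calendar-time diagnosis is not modelled).
#' @return object of class "sim_config".
#' @export
sim_config <- function(n_samples, n_variants, master_seed = 1L,
                       maf_range = c(0.05, 0.5),
                       ld_block_length = 20L, ld_rho = 0,
                       subtype_specs = default_subtypes(),
                       trait_specs = default_traits(),
                       gxe_spec = list(sigma2_g0 = 0.20, sigma2_g1 = 0.05,
                                       sigma2_tau1 = 0,
                                       environment = "quantitative"),
                       covariate_spec = list(age = 0.02, sex = 0.00,
                                             centre = 0.01, batch = 0.00),
                       missing_rate = 0, incident_rate = 0.463) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop("n_samples must be a positive count")
  if (!is.numeric(n_variants) || length(n_variants) != 1L || n_variants < 1)
    stop("n_variants must be a positive count")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (ld_block_length < 1) stop("ld_block_length must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")

  ss <- subtype_specs
  if (nrow(ss)) {
    if (anyDuplicated(ss$name)) stop("duplicate subtype names")
    if (any(ss$prevalence <= 0 | ss$prevalence >= 1))
      stop("subtype prevalences must be in (0, 1)")
    if (any(ss$h2 < 0 | ss$h2 > 1)) stop("subtype h2 must be in [0, 1]")
    if (any(abs(ss$shared_loading) > 1))
      stop("shared loadings must be in [-1, 1]")
    if (is.na(ss$n_causal_shared[1]))
      ss$n_causal_shared <- min(1000L, max(10L, floor(n_variants / 4)))
    if (is.na(ss$n_causal_specific[1]))
      ss$n_causal_specific <- min(300L, max(10L, floor(n_variants / 10)))
    if (any(ss$n_causal_shared > n_variants) ||
        any(ss$n_causal_specific > n_variants))
      stop("causal-set sizes exceed n_variants")
  }
  if (nrow(trait_specs)) {
    if (any(trait_specs$h2 < 0 | trait_specs$h2 > 1))
      stop("trait h2 must be in [0, 1]")
    if (any(abs(trait_specs$rg) > 1)) stop("trait rg must be in [-1, 1]")
  }
  if (!is.null(gxe_spec)) {
    tot <- gxe_spec$sigma2_g0 + gxe_spec$sigma2_g1 + gxe_spec$sigma2_tau1
    if (any(c(gxe_spec$sigma2_g0, gxe_spec$sigma2_g1, gxe_spec$sigma2_tau1) < 0) ||
        tot > 1)
      stop("GxE variance fractions must be non-negative and sum to <= 1")
    gxe_spec$environment <- match.arg(gxe_spec$environment %||% "quantitative",
                                      c("quantitative", "binary"))
  }
  cv <- unlist(covariate_spec)
  if (length(cv) && (any(cv < 0) || sum(cv) >= 1))
    stop("covariate variance fractions must be non-negative and sum to < 1")

  structure(list(
    n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
    master_seed = as.integer(master_seed), maf_range = maf_range,
    ld_block_length = as.integer(ld_block_length), ld_rho = ld_rho,
    subtype_specs = ss, trait_specs = trait_specs, gxe_spec = gxe_spec,
    covariate_spec = covariate_spec, missing_rate = missing_rate,
    incident_rate = incident_rate
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d samples x %d SNPs (seed %d)\n",
              x$n_samples, x$n_variants, x$master_seed))
  cat(sprintf("  MAF in [%.3f, %.3f], LD blocks of %d SNPs, rho = %.2f\n",
              x$maf_range[1], x$maf_range[2], x$ld_block_length, x$ld_rho))
  cat(sprintf("  %d subtypes, %d quantitative traits, GxE: %s\n",
              nrow(x$subtype_specs), nrow(x$trait_specs),
              if (is.null(x$gxe_spec)) "none" else x$gxe_spec$environment))
  invisible(x)
}
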