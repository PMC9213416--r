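# Internal: standardized polygenic score from a causal-column set.
# Effect sizes are i.i.d. normal on frequency-standardized genotypes (the
# GCTA working model); the returned score has empirical unit variance.
polygenic_score <- function(panel, causal_idx) {
  Xs <- standardize_dosages(panel$dosage[, causal_idx, drop = FALSE],
                            freq = panel$variants$maf[causal_idx])
  u <- stats::rnorm(length(causal_idx))
  g <- as.numeric(Xs %*% u)
  as.numeric(scale(g))
}

#' Simulate disease subtypes, quantitative traits and GxE structure
#'
#' Builds the full synthetic cohort on top of a genotype panel. Each subtype
#' liability is a polygenic score (a shared factor weighted by the subtype's
#' loading plus a subtype-specific part), plus covariate effects and a Gaussian
#' residual, standardized to unit variance; a sample is a case when its
#' liability exceeds the threshold qnorm(1 - K_t). Sex-restricted subtypes are
#' recorded as missing (not control) in the excluded sex, and prevalences are
#' within-eligible-sex risks. Quantitative traits are generated with a target
#' heritability and genetic correlation with the shared disease factor. When a
#' GxE specification is present, a quantitative trait with SNP effects
#' modulated by the environment is added:
#' y = g0 + E*g1 + tau*E*eps0 + eps with variance fractions sigma2_g0,
#' sigma2_g1 and sigma2_tau1.
#'
#' @param panel a genotype_panel from [simulate_panel()].
#' @param config the same [sim_config()] used to build the panel.
#' @return object of class "cohort_phenotypes": list with \code{data} (one row
#'   per sample: covariates, subtype indicators, grouped status, incident flag,
#'   traits, environment) and \code{truth} (latent liabilities, genetic values,
#'   causal sets and generative parameters, retained for test harnesses).
#' @export
simulate_phenotypes <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  n <- length(panel$sample_ids)
  m <- nrow(panel$variants)
  if (n != config$n_samples || m != config$n_variants)
    stop("panel and config dimensions disagree")
  ss <- config$subtype_specs
  if (nrow(ss) && any(ss$sex != "both") && is.null(panel$sex))
    stop("sex-restricted subtypes requested but panel lacks sex")

  with_seed(substream_seed(config$master_seed, "phenotypes"), {
    ## --- covariates ---------------------------------------------------------
    age <- round(stats::runif(n, 40, 70))
    centre <- sample.int(5L, n, replace = TRUE)
    batch <- sample.int(10L, n, replace = TRUE)
    smoking <- sample(0:2, n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
    alcohol <- stats::rbinom(n, 1, 0.93)
    tdi <- stats::rnorm(n)
    education <- sample.int(3L, n, replace = TRUE)
    sex_num <- as.integer(panel$sex == "male")

    cv <- config$covariate_spec
    centre_eff <- stats::rnorm(5); centre_eff <- centre_eff / stats::sd(centre_eff)
    batch_eff <- stats::rnorm(10); batch_eff <- batch_eff / stats::sd(batch_eff)
    zs <- function(x) if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, n)
    cov_part <- sqrt(cv$age %||% 0) * zs(age) +
      sqrt(cv$sex %||% 0) * zs(sex_num) +
      sqrt(cv$centre %||% 0) * zs(centre_eff[centre]) +
      sqrt(cv$batch %||% 0) * zs(batch_eff[batch])
    v_cov <- sum(unlist(cv))

    ## --- shared polygenic factor -------------------------------------------
    truth <- list(params = list(subtypes = ss, traits = config$trait_specs,
                                gxe = config$gxe_spec,
                                covariates = config$covariate_spec))
    g0 <- NULL
    if (nrow(ss) || nrow(config$trait_specs)) {
      n_shared <- if (nrow(ss)) ss$n_causal_shared[1]
                  else min(1000L, max(10L, floor(m / 4)))
      shared_set <- sort(sample.int(m, n_shared))
      g0 <- polygenic_score(panel, shared_set)
      truth$shared_causal <- shared_set
      truth$g0 <- g0
    }

    dat <- data.frame(sample_id = panel$sample_ids, sex = panel$sex,
                      age = age, centre = centre, batch = batch,
                      smoking = smoking, alcohol = alcohol, tdi = tdi,
                      education = education, stringsAsFactors = FALSE)

    ## --- subtype liabilities and case status --------------------------------
    liab <- matrix(NA_real_, n, nrow(ss),
                   dimnames = list(NULL, if (nrow(ss)) ss$name))
    gval <- liab
    if (nrow(ss)) {
      for (t in seq_len(nrow(ss))) {
        c_t <- ss$shared_loading[t]
        h2 <- ss$h2[t]
        spec_set <- sort(sample.int(m, ss$n_causal_specific[t]))
        g_spec <- polygenic_score(panel, spec_set)
        g_t <- sqrt(h2) * (c_t * g0 + sqrt(1 - c_t^2) * g_spec)
        resid_v <- max(0, 1 - h2 - v_cov)
        l_t <- g_t + cov_part + stats::rnorm(n, sd = sqrt(resid_v))
        l_t <- as.numeric(scale(l_t))
        liab[, t] <- l_t
        gval[, t] <- g_t
        eligible <- panel$sex == ss$sex[t] | ss$sex[t] == "both"
        status <- ifelse(eligible,
                         as.integer(l_t > stats::qnorm(1 - ss$prevalence[t])),
                         NA_integer_)
        dat[[ss$name[t]]] <- status
        truth[[paste0("causal_", ss$name[t])]] <- spec_set
      }
      sub_mat <- as.matrix(dat[, ss$name, drop = FALSE])
      dat$grouped_status <- as.integer(rowSums(sub_mat, na.rm = TRUE) > 0)
      dat$incident <- ifelse(dat$grouped_status == 1L,
                             stats::rbinom(n, 1, config$incident_rate), 0L)
    }
    truth$liabilities <- liab
    truth$genetic_values <- gval

    ## --- quantitative traits -------------------------------------------------
    ts <- config$trait_specs
    if (nrow(ts)) {
      trait_causal <- min(300L, max(10L, floor(m / 10)))
      for (t in seq_len(nrow(ts))) {
        g_t <- polygenic_score(panel, sort(sample.int(m, trait_causal)))
        h2 <- ts$h2[t]; rg <- ts$rg[t]
        gen <- sqrt(h2) * (rg * g0 + sqrt(1 - rg^2) * g_t)
        dat[[ts$name[t]]] <- gen + stats::rnorm(n, sd = sqrt(1 - h2))
        truth[[paste0("genetic_", ts$name[t])]] <- gen
      }
    }

    ## --- environment and GxE trait ------------------------------------------
    gx <- config$gxe_spec
    if (!is.null(gx)) {
      E <- if (gx$environment == "binary") stats::rbinom(n, 1, 0.5)
           else as.numeric(scale(stats::rnorm(n)))
      gA <- polygenic_score(panel, sort(sample.int(m, min(1000L, m))))
      gB <- polygenic_score(panel, sort(sample.int(m, min(1000L, m))))
      Ez <- if (gx$environment == "binary") (E - mean(E)) / stats::sd(E) else E
      resid_v <- max(0, 1 - gx$sigma2_g0 - gx$sigma2_g1 - gx$sigma2_tau1)
      dat$env <- E
      dat$gxe_trait <- sqrt(gx$sigma2_g0) * gA +
        Ez * (sqrt(gx$sigma2_g1) * gB) +
        sqrt(gx$sigma2_tau1) * Ez * stats::rnorm(n) +
        stats::rnorm(n, sd = sqrt(resid_v))
      truth$gxe <- list(gA = gA, gB = gB, E = E, params = gx)
    }

    structure(list(data = dat, truth = truth,
                   subtypes = if (nrow(ss)) ss$name else character(0)),
              class = "cohort_phenotypes")
  })
}

#' @export
print.cohort_phenotypes <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("cohort_phenotypes: %d samples, %d subtypes\n", n,
              length(x$subtypes)))
  if ("grouped_status" %in% names(x$data))
    cat(sprintf("  grouped cases: %d (%.2f%%)\n", sum(x$data$grouped_status),
                pct(sum(x$data$grouped_status), n)))
  invisible(x)
}

#' Simulate a single quantitative trait with a target heritability
#'
#' Convenience generator used by the variance-component test harnesses:
#' y = g + e with g a standardized polygenic score scaled to variance h2.
#'
#' @param panel a genotype_panel.
#' @param h2 target heritability in [0, 1].
#' @param n_causal number of causal SNPs (default: all).
#' @param seed integer seed.
#' @return list with \code{y}, \code{g} (true genetic values) and
#'   \code{causal} indices.
#' @export
simulate_trait <- function(panel, h2, n_causal = NULL, seed = 1L) {
  stopifnot(h2 >= 0, h2 <= 1)
  m <- nrow(panel$variants)
  n <- length(panel$sample_ids)
  with_seed(seed, {
    idx <- sort(sample.int(m, n_causal %||% m))
    g <- if (h2 > 0) sqrt(h2) * polygenic_score(panel, idx) else numeric(n)
    list(y = g + stats::rnorm(n, sd = sqrt(1 - h2)), g = g, causal = idx)
  })
}

#' Simulate a pair of traits with a target genetic correlation
#'
#' Both traits load on a shared polygenic factor so that their genetic
#' correlation equals \code{rg}; residuals are independent unless
#' \code{re} is given.
#'
#' @param panel a genotype_panel.
#' @param h2 length-2 heritabilities.
#' @param rg target genetic correlation in [-1, 1].
#' @param n_causal causal SNPs per score component (default: all).
#' @param re residual correlation (default 0).
#' @param seed integer seed.
#' @return list with \code{y1}, \code{y2}, and true genetic values.
#' @export
simulate_trait_pair <- function(panel, h2 = c(0.4, 0.4), rg = 0.5,
                                n_causal = NULL, re = 0, seed = 1L) {
  stopifnot(length(h2) == 2, abs(rg) <= 1, abs(re) <= 1)
  m <- nrow(panel$variants)
  n <- length(panel$sample_ids)
  with_seed(seed, {
    nc <- n_causal %||% m
    g0 <- polygenic_score(panel, sort(sample.int(m, nc)))
    ga <- polygenic_score(panel, sort(sample.int(m, nc)))
    gb <- polygenic_score(panel, sort(sample.int(m, nc)))
    s <- if (rg >= 0) 1 else -1
    g1 <- sqrt(h2[1]) * (sqrt(abs(rg)) * g0 + sqrt(1 - abs(rg)) * ga)
    g2 <- sqrt(h2[2]) * (s * sqrt(abs(rg)) * g0 + sqrt(1 - abs(rg)) * gb)
    e0 <- stats::rnorm(n)
    e1 <- sqrt(abs(re)) * e0 + sqrt(1 - abs(re)) * stats::rnorm(n)
    e2 <- sign(re + (re == 0)) * sqrt(abs(re)) * e0 +
      sqrt(1 - abs(re)) * stats::rnorm(n)
    list(y1 = g1 + sqrt(1 - h2[1]) * e1, y2 = g2 + sqrt(1 - h2[2]) * e2,
         g1 = g1, g2 = g2)
  })
}

#' Simulate a phenotype whose SNP effects differ between two environments
#'
#' Generates a binary environment label and a phenotype whose per-stratum SNP
#' effect vectors have genetic correlation \code{rg_strata}; used to exercise
#' the stratified (bivariate) GxE analysis. \code{rg_strata = 1} is the no-GxE
#' null (identical effects in both strata).
#'
#' @param panel a genotype_panel.
#' @param h2 per-stratum heritability (scalar or length 2).
#' @param rg_strata genetic correlation of SNP effects across strata.
#' @param prevalence if non-NULL, threshold the liability at this prevalence to
#'   produce a binary phenotype; otherwise the liability itself is returned.
#' @param n_causal causal SNPs per component (default: all).
#' @param seed integer seed.
#' @return list with \code{y}, \code{env} (0/1 labels) and truth values.
#' @export
simulate_gxe_strata <- function(panel, h2 = 0.5, rg_strata = 1,
                                prevalence = NULL, n_causal = NULL, seed = 1L) {
  h2 <- rep(h2, length.out = 2)
  stopifnot(abs(rg_strata) <= 1)
  m <- nrow(panel$variants)
  n <- length(panel$sample_ids)
  with_seed(seed, {
    env <- stats::rbinom(n, 1, 0.5)
    nc <- n_causal %||% m
    g0 <- polygenic_score(panel, sort(sample.int(m, nc)))
    ga <- polygenic_score(panel, sort(sample.int(m, nc)))
    gb <- polygenic_score(panel, sort(sample.int(m, nc)))
    a <- sqrt(abs(rg_strata)); b <- sqrt(1 - abs(rg_strata))
    g_s0 <- a * g0 + b * ga
    g_s1 <- sign(rg_strata + (rg_strata == 0)) * a * g0 + b * gb
    g <- ifelse(env == 0, sqrt(h2[1]) * g_s0, sqrt(h2[2]) * g_s1)
    l <- g + stats::rnorm(n) *
      ifelse(env == 0, sqrt(1 - h2[1]), sqrt(1 - h2[2]))
    y <- if (is.null(prevalence)) l
         else as.integer(l > stats::qnorm(1 - prevalence, sd = stats::sd(l)))
    list(y = y, env = env, liability = l, g = g)
  })
}
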