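#' Build a pipeline run configuration
#'
#' Bundles the simulation configuration, QC thresholds, analysis toggles and
#' model choices for [run_pipeline()]. Every defaulted value is materialized
#' in the returned object, which is hashed into the run provenance.
#'
#' @param sim a [sim_config()] object.
#' @param qc a [qc_thresholds()] object.
#' @param toggles named logical list enabling stages: greml, gwas, ldsc,
#'   pheno, loo, gxe.
#' @param gwas_model "linear" or "logistic".
#' @param clump_r2,clump_window_bp,p_threshold clumping parameters.
#' @param ld_window_bp LD-score window.
#' @param n_pcs principal components used as covariates.
#' @param n_blocks LD-score jackknife blocks.
#' @param out_dir optional directory for stage outputs (TSV/PLINK/GRM).
#' @return object of class "run_config".
#' @export
run_config <- function(sim, qc = qc_thresholds(),
                       toggles = list(greml = TRUE, gwas = TRUE, ldsc = TRUE,
                                      pheno = TRUE, loo = FALSE, gxe = FALSE),
                       gwas_model = "linear", clump_r2 = 0.1,
                       clump_window_bp = 1e6, p_threshold = 5e-8,
                       ld_window_bp = 1e6, n_pcs = 10, n_blocks = 200,
                       out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(qc, "qc_thresholds"))
  defaults <- list(greml = TRUE, gwas = TRUE, ldsc = TRUE, pheno = TRUE,
                   loo = FALSE, gxe = FALSE)
  defaults[names(toggles)] <- toggles
  structure(list(sim = sim, qc = qc, toggles = defaults,
                 gwas_model = gwas_model, clump_r2 = clump_r2,
                 clump_window_bp = clump_window_bp, p_threshold = p_threshold,
                 ld_window_bp = ld_window_bp, n_pcs = n_pcs,
                 n_blocks = n_blocks, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order: simulate, QC, GRM (with
#' relatedness pruning and PC-outlier filtering), GREML heritability of the
#' grouped phenotype (observed and liability scales), GWAS with inflation
#' diagnostics and LD clumping, LD-score regression heritability,
#' phenotypic correlations, optional leave-one-out genetic-correlation grid
#' and optional gene-environment interaction analyses. Identical
#' configuration and seed give an identical report.
#'
#' @param config a [run_config()] object.
#' @return object of class "study_report": per-stage results plus provenance
#'   (configuration hash, master seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tg <- config$toggles
  report <- list(provenance = list(
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    master_seed = config$sim$master_seed,
    package_version = as.character(utils::packageVersion("grouph2")),
    stages = names(which(unlist(tg)))))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  panel <- simulate_panel(config$sim)
  cohort <- simulate_phenotypes(panel, config$sim)
  qc <- apply_qc(panel, config$qc)
  report$qc <- qc$report
  panel_qc <- qc$panel
  keep_samples <- match(panel_qc$sample_ids, panel$sample_ids)
  dat <- cohort$data[keep_samples, , drop = FALSE]

  grm <- compute_grm(panel_qc)
  kept <- prune_related(grm, relatedness_cutoff(grm, config$qc$relatedness_max),
                        seed = substream_seed(config$sim$master_seed, "prune"))
  grm <- subset_grm(grm, kept)
  pcf <- pc_outlier_filter(grm, n_pcs = min(config$n_pcs,
                                            length(kept) - 1),
                           sd_limit = config$qc$pc_sd_limit)
  grm <- subset_grm(grm, pcf$kept)
  panel_qc <- subset_panel(panel_qc, samples = pcf$kept)
  dat <- dat[match(pcf$kept, dat$sample_id), , drop = FALSE]
  pcs <- pcf$pcs[pcf$kept, , drop = FALSE]
  report$n_samples <- nrow(dat)
  report$n_variants <- nrow(panel_qc$variants)

  y <- dat$grouped_status
  covs <- cbind(age = dat$age, sex = as.integer(dat$sex == "male"),
                tdi = dat$tdi, smoking = dat$smoking, alcohol = dat$alcohol,
                education = dat$education, pcs)
  P <- mean(y)
  report$descriptives <- data.frame(
    n = nrow(dat), cases = sum(y), controls = sum(y == 0),
    case_pct = pct(sum(y), nrow(dat)))

  if (isTRUE(tg$greml)) {
    fit <- reml_fit(y, grm, covariates = covs)
    fit <- observed_to_liability(fit, K = P, P = P)
    report$greml <- fit
  }
  if (isTRUE(tg$gwas)) {
    assoc <- association_scan(panel_qc, y, covariates = covs,
                              model = config$gwas_model)
    infl <- genomic_inflation(assoc)
    loci <- clump_loci(assoc, panel_qc, config$p_threshold, config$clump_r2,
                       config$clump_window_bp)
    report$gwas <- list(assoc = assoc, inflation = infl, loci = loci)
    if (!is.null(out)) {
      write_assoc(assoc, file.path(out, "gwas_grouped.tsv"))
      write_sumstats(assoc_to_sumstats(assoc),
                     file.path(out, "gwas_grouped.sumstats.tsv"))
    }
  }
  if (isTRUE(tg$ldsc)) {
    lds <- compute_ld_scores(panel_qc, config$ld_window_bp)
    assoc <- report$gwas$assoc %||%
      association_scan(panel_qc, y, covariates = covs,
                       model = config$gwas_model)
    fit <- ldsc_h2(assoc_to_sumstats(assoc), lds,
                   n_blocks = config$n_blocks, K = P, P = P)
    report$ldsc <- fit
    report$ldscores <- lds
    if (!is.null(out)) write_ldscore(lds, file.path(out, "panel"))
  }
  if (isTRUE(tg$pheno)) {
    traits <- intersect(config$sim$trait_specs$name, names(dat))
    rows <- lapply(traits, function(tr) {
      pc <- phenotypic_correlation(dat[[tr]], y)
      data.frame(trait = tr, r = pc$r, se = pc$se_r, p = pc$p, n = pc$n)
    })
    report$pheno_correlations <- do.call(rbind, rows)
  }
  if (isTRUE(tg$loo)) {
    lds <- report$ldscores %||% compute_ld_scores(panel_qc, config$ld_window_bp)
    statuses <- dat[, intersect(cohort$subtypes, names(dat)), drop = FALSE]
    report$loo <- loo_rg_grid(panel_qc, statuses, lds, covariates = covs)
  }
  if (isTRUE(tg$gxe) && !is.null(config$sim$gxe_spec)) {
    lds <- report$ldscores %||% compute_ld_scores(panel_qc, config$ld_window_bp)
    ss <- interaction_scan(panel_qc, dat$gxe_trait, dat$env,
                           covariates = covs)
    report$gxesum <- gxesum_fit(ss, lds, n_blocks = config$n_blocks)
  }
  if (!is.null(out)) {
    saved <- config
    saved$out_dir <- NULL
    writeLines(c(paste("config_hash", report$provenance$config_hash),
                 utils::capture.output(utils::str(saved))),
               file.path(out, "run_config.txt"))
  }
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report (seed %d, config %s)\n",
              x$provenance$master_seed, x$provenance$config_hash))
  cat(sprintf("  stages: %s\n", paste(x$provenance$stages, collapse = ", ")))
  if (!is.null(x$descriptives))
    cat(sprintf("  %d samples, %d grouped cases (%.2f%%)\n",
                x$descriptives$n, x$descriptives$cases, x$descriptives$case_pct))
  if (!is.null(x$greml))
    cat(sprintf("  GREML h2 (liability) = %.4f (se %.4f)\n",
                x$greml$h2_liability, x$greml$se_h2_liability))
  if (!is.null(x$ldsc))
    cat(sprintf("  LDSC  h2 (liability) = %.4f (se %.4f)\n",
                x$ldsc$h2_liability, x$ldsc$se_h2_liability))
  if (!is.null(x$gwas))
    cat(sprintf("  GWAS: lambda_1000 = %.4f, %d independent loci\n",
                x$gwas$inflation$lambda_1000, nrow(x$gwas$loci)))
  invisible(x)
}

#' Near-equal split sizes for split-sample meta-analysis
#'
#' Partitions n samples into k groups whose sizes differ by at most one,
#' with the larger groups last.
#'
#' @param n total sample count.
#' @param k number of splits (>= 2).
#' @return integer vector of k sizes summing to n.
#' @export
split_sizes <- function(n, k) {
  if (k < 2) stop("need at least 2 splits")
  if (k > n) stop("more splits than samples")
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[k - seq_len(r) + 1] <- sizes[k - seq_len(r) + 1] + 1L
  as.integer(sizes)
}

#' Split-sample GREML with meta-analysis pooling
#'
#' Randomly partitions the cohort into k near-equal splits, fits the
#' univariate GREML model in each, and pools the estimates: inverse-variance
#' weighting for the point estimate and Fisher's method for the p-values.
#' Mirrors the strategy of subdividing a large cohort to bound the cubic
#' REML cost.
#'
#' @param y phenotype vector.
#' @param grm a [compute_grm()] object aligned with y.
#' @param covariates optional covariate matrix.
#' @param k number of splits.
#' @param seed seed for the random partition.
#' @param K optional prevalence: pool on the liability scale with K = P.
#' @return list with \code{per_split} (heritability estimates), \code{meta}
#'   (a [split_meta()] object on h2), and \code{sizes}.
#' @export
split_sample_runner <- function(y, grm, covariates = NULL, k = 2, seed = 1L,
                                K = NULL) {
  n <- length(y)
  sizes <- split_sizes(n, k)
  if (min(sizes) < 50) stop("a split would fall below the GREML minimum n")
  idx <- with_seed(seed, sample.int(n))
  assign_split <- rep(seq_len(k), times = sizes)
  fits <- lapply(seq_len(k), function(s) {
    i <- sort(idx[assign_split == s])
    fit <- reml_fit(y[i], subset_grm(grm, i),
                    covariates = if (!is.null(covariates))
                      covariates[i, , drop = FALSE])
    if (!is.null(K)) {
      P <- mean(y[i])
      fit <- observed_to_liability(fit, K = K, P = P)
    }
    fit
  })
  if (!is.null(K)) {
    est <- vapply(fits, function(f) f$h2_liability, numeric(1))
    se <- vapply(fits, function(f) f$se_h2_liability, numeric(1))
  } else {
    est <- vapply(fits, function(f) f$h2_obs, numeric(1))
    se <- vapply(fits, function(f) f$se_h2, numeric(1))
  }
  p <- vapply(fits, function(f) f$p_h2, numeric(1))
  list(per_split = fits, meta = split_meta(est, se, p), sizes = sizes)
}
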