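#' Quality-control thresholds for genotype panels
#'
#' Defaults follow a standard biobank-scale QC cascade: sample and SNP call
#' rate at least 0.95, imputation INFO at least 0.6, MAF at least 0.01,
#' Hardy-Weinberg exact mid-p at least 1e-7, pairwise genomic relatedness at
#' most 0.05, principal-component outliers beyond 6 SD removed, and
#' cross-release genotype discordance at most 0.05.
#'
#' @param sample_call_rate_min minimum per-sample call rate.
#' @param snp_call_rate_min minimum per-SNP call rate.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE exact mid-p value.
#' @param info_min minimum imputation INFO score.
#' @param relatedness_max maximum retained pairwise GRM entry.
#' @param pc_sd_limit PC1/PC2 outlier limit in SD units.
#' @param discordance_max maximum cross-release discordance rate.
#' @return object of class "qc_thresholds".
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95, snp_call_rate_min = 0.95,
                          maf_min = 0.01, hwe_p_min = 1e-7, info_min = 0.6,
                          relatedness_max = 0.05, pc_sd_limit = 6,
                          discordance_max = 0.05) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
             hwe_p_min = hwe_p_min, info_min = info_min,
             relatedness_max = relatedness_max, pc_sd_limit = pc_sd_limit,
             discordance_max = discordance_max)
  probs <- c("sample_call_rate_min", "snp_call_rate_min", "maf_min",
             "hwe_p_min", "info_min", "discordance_max")
  for (p in probs)
    if (th[[p]] < 0 || th[[p]] > 1) stop(sprintf("%s outside [0, 1]", p))
  if (th$relatedness_max <= 0) stop("relatedness_max must be positive")
  if (th$pc_sd_limit <= 0) stop("pc_sd_limit must be positive")
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg exact mid-p test from genotype counts
#'
#' Exact test over the conditional distribution of heterozygote counts given
#' the allele counts (Wigginton's recurrence), returned as a mid-p value:
#' half the probability of the observed heterozygote count plus the
#' probabilities of all less likely counts. The mid-p variant is preferred
#' over the chi-square approximation for rare genotypes.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return mid-p value.
#' @export
hwe_midp <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  rare <- 2 * min(n_aa, n_bb) + n_ab   # count of the rarer allele
  # heterozygote counts share the parity of the rare-allele count
  het_values <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- numeric(length(het_values))
  # start from the mode and apply the recurrence in both directions
  mid <- rare * (2 * n - rare) / (2 * n - 1)
  start <- het_values[which.min(abs(het_values - mid))]
  i0 <- match(start, het_values)
  probs[i0] <- 1
  if (i0 < length(het_values)) {
    for (i in seq(i0, length(het_values) - 1)) {
      het <- het_values[i]
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      # P(het+2)/P(het) = 4*hom_r*hom_c / ((het+2)*(het+1))
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((het + 2) * (het + 1))
    }
  }
  if (i0 > 1) {
    for (i in seq(i0, 2)) {
      het <- het_values[i]
      # P(het-2)/P(het) = het*(het-1) / (4*(hom_r+1)*(hom_c+1))
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i - 1] <- probs[i] * het * (het - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- match(n_ab, het_values)
  p_obs <- probs[obs]
  sum(probs[probs < p_obs]) + 0.5 * sum(probs[probs == p_obs])
}

hwe_midp_vec <- function(dosage) {
  vapply(seq_len(ncol(dosage)), function(j) {
    x <- dosage[, j]
    x <- x[!is.na(x)]
    hwe_midp(sum(x == 2L), sum(x == 1L), sum(x == 0L))
  }, numeric(1))
}

#' Apply the genotype/sample QC cascade
#'
#' Filters are applied in a fixed, logged order: sample call rate, SNP call
#' rate, INFO score, MAF, HWE exact mid-p, then ambiguous (A/T, C/G) and
#' duplicated (same chromosome, position and allele set) variants. The cascade
#' is idempotent. MAF is recomputed from observed dosages, so monomorphic
#' variants fall to the MAF filter.
#'
#' @param panel a genotype_panel.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with \code{panel} (the filtered genotype_panel) and
#'   \code{report} (removal counts per rule, in application order).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$sample_ids) == 0 || nrow(panel$variants) == 0)
    stop("empty panel")
  th <- thresholds
  report <- c(sample_call_rate = 0L, snp_call_rate = 0L, info = 0L, maf = 0L,
              hwe = 0L, ambiguous = 0L, duplicate = 0L)

  scr <- rowMeans(!is.na(panel$dosage))
  keep_s <- scr >= th$sample_call_rate_min
  report["sample_call_rate"] <- sum(!keep_s)
  if (!any(keep_s)) stop("empty panel: all samples removed by call-rate filter")
  panel <- subset_panel(panel, samples = which(keep_s))

  vcr <- colMeans(!is.na(panel$dosage))
  keep_v <- vcr >= th$snp_call_rate_min
  report["snp_call_rate"] <- sum(!keep_v)
  panel <- drop_variants(panel, keep_v)

  keep_v <- panel$variants$info >= th$info_min
  report["info"] <- sum(!keep_v)
  panel <- drop_variants(panel, keep_v)

  p_obs <- colMeans(panel$dosage, na.rm = TRUE) / 2
  maf_obs <- pmin(p_obs, 1 - p_obs)
  keep_v <- is.finite(maf_obs) & maf_obs >= th$maf_min
  report["maf"] <- sum(!keep_v)
  panel <- drop_variants(panel, keep_v)

  keep_v <- hwe_midp_vec(panel$dosage) >= th$hwe_p_min
  report["hwe"] <- sum(!keep_v)
  panel <- drop_variants(panel, keep_v)

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- panel$variants$A2 == comp[panel$variants$A1]
  report["ambiguous"] <- sum(ambiguous)
  panel <- drop_variants(panel, !ambiguous)

  key <- paste(panel$variants$CHR, panel$variants$BP,
               pmin(panel$variants$A1, panel$variants$A2),
               pmax(panel$variants$A1, panel$variants$A2))
  dup <- duplicated(key)
  report["duplicate"] <- sum(dup)
  panel <- drop_variants(panel, !dup)

  list(panel = panel, report = report)
}

drop_variants <- function(panel, keep) {
  if (!any(keep)) stop("empty panel: all variants removed by QC")
  subset_panel(panel, variants = which(keep))
}

#' Cross-release genotype discordance filter
#'
#' Computes per-sample and per-variant mismatch fractions between two genotype
#' panels over jointly non-missing entries on the shared sample/variant space,
#' and removes entities whose discordance exceeds \code{max_rate}.
#'
#' @param panel_a,panel_b genotype_panels sharing sample and variant ids.
#' @param max_rate maximum tolerated discordance fraction.
#' @return list with \code{kept_samples}, \code{kept_variants},
#'   \code{sample_rates}, \code{variant_rates}.
#' @export
discordance_filter <- function(panel_a, panel_b, max_rate = 0.05) {
  ids <- intersect(panel_a$sample_ids, panel_b$sample_ids)
  snps <- intersect(panel_a$variants$SNP, panel_b$variants$SNP)
  if (length(ids) == 0 || length(snps) == 0)
    stop("no overlap between panels")
  a <- subset_panel(panel_a, samples = ids, variants = snps)$dosage
  b <- subset_panel(panel_b, samples = ids, variants = snps)$dosage
  both <- !is.na(a) & !is.na(b)
  mism <- (a != b) & both
  sr <- rowSums(mism) / pmax(rowSums(both), 1)
  vr <- colSums(mism) / pmax(colSums(both), 1)
  list(kept_samples = ids[sr <= max_rate], kept_variants = snps[vr <= max_rate],
       sample_rates = stats::setNames(sr, ids),
       variant_rates = stats::setNames(vr, snps))
}
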