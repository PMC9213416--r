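#' Simulate a genotype panel with block LD under Hardy-Weinberg equilibrium
#'
#' Genotypes are generated from a Gaussian-copula haplotype model: within each
#' LD block every haplotype carries a latent AR(1) Gaussian process with
#' parameter \code{ld_rho}; the haplotype allele at SNP j is 1 when the latent
#' value falls below the p_j-quantile, so each SNP has allele-1 frequency p_j,
#' Hardy-Weinberg holds exactly per SNP, and adjacent-SNP LD decays
#' geometrically within a block while blocks are independent. This gives
#' closed-form control of LD decay without a real reference map.
#'
#' @param config a [sim_config()] object.
#' @return object of class "genotype_panel": list with \code{sample_ids},
#'   \code{sex}, \code{variants} (CHR, BP, SNP, A1, A2, maf, info) and
#'   \code{dosage}, an n x m integer matrix of allele-1 counts (NA = missing).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m <- config$n_variants
  with_seed(substream_seed(config$master_seed, "panel"), {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    L <- config$ld_block_length
    block <- rep(seq_len(ceiling(m / L)), each = L)[seq_len(m)]
    n_block <- max(block)
    # positions: blocks dealt round-robin over 22 autosomes, 5 kb SNP spacing
    chr_of_block <- ((seq_len(n_block) - 1L) %% 22L) + 1L
    chr <- chr_of_block[block]
    bp <- integer(m)
    for (cc in unique(chr)) {
      idx <- which(chr == cc)
      bp[idx] <- seq_along(idx) * 5000L
    }
    pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                   c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
    al <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]

    dosage <- matrix(0L, n, m)
    rho <- config$ld_rho
    for (b in seq_len(n_block)) {
      cols <- which(block == b)
      Lb <- length(cols)
      thr <- stats::qnorm(maf[cols])
      if (rho == 0) {
        Z1 <- matrix(stats::rnorm(n * Lb), n, Lb)
        Z2 <- matrix(stats::rnorm(n * Lb), n, Lb)
      } else {
        innov1 <- matrix(stats::rnorm(n * Lb), n, Lb)
        innov2 <- matrix(stats::rnorm(n * Lb), n, Lb)
        Z1 <- innov1; Z2 <- innov2
        s <- sqrt(1 - rho^2)
        for (j in seq_len(Lb)[-1]) {
          Z1[, j] <- rho * Z1[, j - 1] + s * innov1[, j]
          Z2[, j] <- rho * Z2[, j - 1] + s * innov2[, j]
        }
      }
      h1 <- sweep(Z1, 2, thr, "<")
      h2 <- sweep(Z2, 2, thr, "<")
      dosage[, cols] <- h1 + h2
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * m) < config$missing_rate
      dosage[miss] <- NA_integer_
    }
    sex <- sample(c("female", "male"), n, replace = TRUE)
    panel <- structure(list(
      sample_ids = sprintf("id%06d", seq_len(n)),
      sex = sex,
      variants = data.frame(
        CHR = chr, BP = bp, SNP = sprintf("snp%07d", seq_len(m)),
        A1 = al[, 1], A2 = al[, 2], maf = maf,
        info = stats::runif(m, 0.85, 1), stringsAsFactors = FALSE),
      dosage = dosage
    ), class = "genotype_panel")
    panel
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants\n",
              length(x$sample_ids), nrow(x$variants)))
  cat(sprintf("  chromosomes %s; mean MAF %.3f; missing %.4f\n",
              paste(range(x$variants$CHR), collapse = "-"),
              mean(x$variants$maf), mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype panel by samples and/or variants
#'
#' @param panel a genotype_panel.
#' @param samples sample indices or ids to keep (NULL = all).
#' @param variants variant indices or SNP ids to keep (NULL = all).
#' @return the subset genotype_panel.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(panel$sample_ids)
        else if (is.character(samples)) match(samples, panel$sample_ids)
        else samples
  vi <- if (is.null(variants)) seq_len(nrow(panel$variants))
        else if (is.character(variants)) match(variants, panel$variants$SNP)
        else variants
  if (anyNA(si)) stop("unknown sample ids in subset")
  if (anyNA(vi)) stop("unknown variant ids in subset")
  structure(list(
    sample_ids = panel$sample_ids[si], sex = panel$sex[si],
    variants = panel$variants[vi, , drop = FALSE],
    dosage = panel$dosage[si, vi, drop = FALSE]
  ), class = "genotype_panel")
}

# Column-standardize dosages using observed allele frequencies; missing values
# are mean-imputed (used for GRM/PCA/LD, never for association testing).
standardize_dosages <- function(dosage, freq = NULL) {
  p <- freq %||% (colMeans(dosage, na.rm = TRUE) / 2)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    bad <- which(!is.finite(p) | p <= 0 | p >= 1)
    stop(sprintf("zero-variance or all-missing SNP at column(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  X <- sweep(dosage, 2, 2 * p)
  if (anyNA(X)) X[is.na(X)] <- 0   # mean-imputation after centering
  sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
}
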