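#' Construct the genomic relationship matrix
#'
#' Frequency-standardized estimator
#' A_jk = (1/M) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' with allele frequencies p_i estimated from the panel unless supplied.
#' Missing dosages are mean-imputed per SNP (for the GRM only; association
#' testing elsewhere uses observed genotypes).
#'
#' @param panel a genotype_panel (QC'd).
#' @param freq optional vector of allele-1 frequencies to standardize with.
#' @return object of class "grm": list with \code{sample_ids}, \code{A}
#'   (symmetric n x n matrix) and \code{M} (number of variants used).
#' @export
compute_grm <- function(panel, freq = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  M <- nrow(panel$variants)
  Xs <- standardize_dosages(panel$dosage, freq = freq)
  A <- tcrossprod(Xs) / M
  structure(list(sample_ids = panel$sample_ids, A = A, M = M), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$sample_ids)
  offd <- x$A[upper.tri(x$A)]
  cat(sprintf("grm: %d samples from %d variants\n", n, x$M))
  cat(sprintf("  mean diagonal %.4f; off-diagonal mean %.5f sd %.5f\n",
              mean(diag(x$A)), mean(offd), stats::sd(offd)))
  invisible(x)
}

#' Prune one member of each overly related sample pair
#'
#' Greedy over pairs sorted by descending relatedness: for each pair above the
#' cutoff whose members are both still retained, one member is removed by a
#' seeded random coin flip. The output is verified post hoc: no retained pair
#' exceeds the cutoff.
#'
#' @param grm a [compute_grm()] object.
#' @param cutoff maximum retained pairwise relationship (default 0.05).
#' @param seed seed for the random within-pair choice.
#' @return character vector of retained sample ids.
#' @export
prune_related <- function(grm, cutoff = 0.05, seed = 1L) {
  stopifnot(inherits(grm, "grm"))
  if (cutoff <= 0) stop("cutoff must be positive")
  A <- grm$A
  idx <- which(upper.tri(A) & A > cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) return(grm$sample_ids)
  ord <- order(A[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  removed <- logical(nrow(A))
  with_seed(seed, {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (removed[i] || removed[j]) next
      removed[if (stats::runif(1) < 0.5) i else j] <- TRUE
    }
  })
  kept <- which(!removed)
  stopifnot(max(A[kept, kept][upper.tri(A[kept, kept])], -Inf) <= cutoff)
  grm$sample_ids[kept]
}

#' Principal-component outlier filter from the GRM eigendecomposition
#'
#' PCs are the leading eigenvectors of the GRM scaled by the square root of
#' their eigenvalues. Samples whose PC1 or PC2 coordinate falls outside
#' \code{sd_limit} standard deviations of the mean are flagged as population
#' outliers. The PCs are returned for reuse as association covariates.
#'
#' @param grm a [compute_grm()] object.
#' @param n_pcs number of leading PCs to return.
#' @param sd_limit outlier limit in SD units (default 6).
#' @return list with \code{kept} ids, \code{removed} ids and \code{pcs}
#'   (n x n_pcs matrix, rownames = sample ids).
#' @export
pc_outlier_filter <- function(grm, n_pcs = 10, sd_limit = 6) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$sample_ids)
  if (n_pcs > n) stop("n_pcs exceeds GRM rank")
  eg <- eigen(grm$A, symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(n_pcs)], 0)
  pcs <- sweep(eg$vectors[, seq_len(n_pcs), drop = FALSE], 2, sqrt(ev), "*")
  rownames(pcs) <- grm$sample_ids
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  out <- rep(FALSE, n)
  for (k in seq_len(min(2, n_pcs))) {
    z <- (pcs[, k] - mean(pcs[, k])) / stats::sd(pcs[, k])
    out <- out | abs(z) > sd_limit
  }
  list(kept = grm$sample_ids[!out], removed = grm$sample_ids[out], pcs = pcs)
}

#' Noise-aware relatedness pruning cutoff
#'
#' The production cutoff (0.05) presumes a GRM estimated from enough markers
#' that its off-diagonal sampling noise is far below 0.05. On small panels
#' the noise floor (roughly 1/sqrt(effective markers)) can reach or exceed
#' the cutoff, and thresholding at 0.05 would remove most of an entirely
#' unrelated cohort through estimator noise alone. This helper raises the
#' cutoff to \code{n_sd} standard deviations of the observed off-diagonal
#' distribution whenever that floor is higher than \code{base}, so only pairs
#' incompatible with unrelatedness are pruned.
#'
#' @param grm a [compute_grm()] object.
#' @param base nominal cutoff (default 0.05).
#' @param n_sd noise-floor multiplier (default 6).
#' @return the cutoff to pass to [prune_related()].
#' @export
relatedness_cutoff <- function(grm, base = 0.05, n_sd = 6) {
  offd <- grm$A[upper.tri(grm$A)]
  max(base, n_sd * stats::sd(offd))
}

#' Subset a GRM to a set of samples
#'
#' @param grm a grm object.
#' @param ids sample ids or indices to keep.
#' @return the subset grm.
#' @export
subset_grm <- function(grm, ids) {
  i <- if (is.character(ids)) match(ids, grm$sample_ids) else ids
  if (anyNA(i)) stop("unknown sample ids")
  structure(list(sample_ids = grm$sample_ids[i], A = grm$A[i, i, drop = FALSE],
                 M = grm$M), class = "grm")
}
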