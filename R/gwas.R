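#' Per-SNP association scan
#'
#' Fits, for every SNP, phenotype ~ intercept + covariates + dosage(A1) and
#' reports the Wald statistics. Two models are available: "logistic"
#' (iteratively reweighted least squares, 25-iteration cap, for binary
#' phenotypes) and "linear", which regresses the phenotype (including a 0/1
#' disease indicator, giving linear-probability-scale betas) on the dosage.
#' Missing genotypes are excluded per SNP (NMISS is the number of samples with
#' an observed genotype); when the panel has no missing dosages the linear
#' model uses a vectorized residualization fast path. Zero-variance SNPs are
#' skipped with a log entry; separated logistic fits are reported as NA with a
#' flag.
#'
#' @param panel a genotype_panel.
#' @param y phenotype vector aligned with the panel (0/1 for logistic).
#' @param covariates optional numeric covariate matrix.
#' @param model "linear" or "logistic".
#' @return data.frame (class "association_table") with columns CHR, BP, SNP,
#'   A1, A2, P, BETA, SE, STAT, NMISS; attributes: model, n_cases, n_controls,
#'   covariates, skipped (zero-variance SNP ids), flagged (separation).
#' @export
association_scan <- function(panel, y, covariates = NULL,
                             model = c("linear", "logistic")) {
  model <- match.arg(model)
  stopifnot(inherits(panel, "genotype_panel"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(length(panel$sample_ids) == n)
  v <- panel$variants
  m <- nrow(v)
  C <- cbind(intercept = rep(1, n), covariates)
  # collinearity guard: drop constant covariate columns (e.g. sex in a
  # sex-restricted subtype scan)
  keepc <- c(TRUE, if (ncol(C) > 1)
    apply(C[, -1, drop = FALSE], 2, function(z) stats::sd(z) > 0))
  C <- C[, keepc, drop = FALSE]
  if (qr(C)$rank < ncol(C)) stop("covariates are not full rank")
  binary <- all(y %in% c(0, 1))
  if (model == "logistic" && !binary)
    stop("logistic model requires a binary phenotype")

  beta <- se <- rep(NA_real_, m)
  nmiss <- integer(m)
  skipped <- character(0)
  flagged <- character(0)
  has_missing <- anyNA(panel$dosage)

  if (model == "linear" && !has_missing) {
    qC <- qr(C)
    yr <- qr.resid(qC, y)
    yry <- sum(yr^2)
    df <- n - ncol(C) - 1
    chunk <- 2000L
    for (a in seq(1, m, by = chunk)) {
      b <- min(a + chunk - 1L, m)
      G <- panel$dosage[, a:b, drop = FALSE]
      storage.mode(G) <- "double"
      Gr <- qr.resid(qC, G)
      xx <- colSums(Gr^2)
      ok <- xx > 1e-12
      xy <- colSums(Gr * yr)
      bb <- ifelse(ok, xy / xx, NA_real_)
      rss <- pmax(yry - bb^2 * xx, 0)
      ss <- sqrt(rss / df / xx)
      beta[a:b] <- bb
      se[a:b] <- ifelse(ok, ss, NA_real_)
      nmiss[a:b] <- n
      skipped <- c(skipped, v$SNP[a:b][!ok])
    }
  } else {
    for (j in seq_len(m)) {
      g <- panel$dosage[, j]
      obs <- !is.na(g)
      nmiss[j] <- sum(obs)
      gv <- as.numeric(g[obs])
      if (stats::sd(gv) < 1e-12) { skipped <- c(skipped, v$SNP[j]); next }
      Xj <- cbind(C[obs, , drop = FALSE], g = gv)
      if (model == "linear") {
        fit <- stats::lm.fit(Xj, y[obs])
        rss <- sum(fit$residuals^2)
        XtXi <- chol2inv(chol(crossprod(Xj)))
        s2 <- rss / (nmiss[j] - ncol(Xj))
        beta[j] <- fit$coefficients["g"]
        se[j] <- sqrt(s2 * XtXi[ncol(Xj), ncol(Xj)])
      } else {
        fit <- suppressWarnings(
          stats::glm.fit(Xj, y[obs], family = stats::binomial(),
                         control = list(maxit = 25)))
        cf <- fit$coefficients["g"]
        vc <- tryCatch(chol2inv(chol(crossprod(sqrt(fit$weights) * Xj))),
                       error = function(e) NULL)
        sej <- if (is.null(vc)) NA_real_ else sqrt(vc[ncol(Xj), ncol(Xj)])
        if (!fit$converged || is.na(sej) || abs(cf) > 15 || sej > 100) {
          flagged <- c(flagged, v$SNP[j])
          next
        }
        beta[j] <- cf
        se[j] <- sej
      }
    }
  }
  stat <- beta / se
  pval <- if (model == "linear")
    2 * stats::pt(-abs(stat), df = pmax(nmiss - ncol(C) - 1, 1))
  else p_from_z(stat)
  out <- data.frame(CHR = v$CHR, BP = v$BP, SNP = v$SNP, A1 = v$A1, A2 = v$A2,
                    P = pval, BETA = beta, SE = se, STAT = stat,
                    NMISS = nmiss, stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  attr(out, "model") <- model
  attr(out, "n_cases") <- if (binary) sum(y == 1) else NA_integer_
  attr(out, "n_controls") <- if (binary) sum(y == 0) else NA_integer_
  attr(out, "covariates") <- colnames(C)[-1]
  attr(out, "skipped") <- skipped
  attr(out, "flagged") <- flagged
  out
}

#' Rescale a genomic inflation factor to a 1000-case/1000-control study
#'
#' lambda_1000 = 1 + (lambda - 1) * (1/n_cases + 1/n_controls) /
#' (1/1000 + 1/1000).
#'
#' @param lambda observed genomic inflation factor.
#' @param n_cases,n_controls study sample sizes.
#' @return the rescaled inflation factor.
#' @export
lambda_1000 <- function(lambda, n_cases, n_controls) {
  if (n_cases <= 0 || n_controls <= 0) stop("need positive case/control counts")
  1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (2 / 1000)
}

#' Genomic inflation diagnostics for an association scan
#'
#' The inflation factor lambda is the median of the per-SNP chi-square
#' statistics (STAT^2) divided by the median of the 1-df chi-square
#' distribution (qchisq(0.5, 1) = 0.4549364), and lambda_1000 rescales it to
#' an equivalent 1000-case/1000-control study. Also returns
#' quantile-quantile pairs of expected and observed -log10 p.
#'
#' @param assoc an association table from [association_scan()].
#' @param n_cases,n_controls counts (defaults: taken from the scan attributes).
#' @return object of class "inflation_summary".
#' @export
genomic_inflation <- function(assoc, n_cases = NULL, n_controls = NULL) {
  n_cases <- n_cases %||% attr(assoc, "n_cases")
  n_controls <- n_controls %||% attr(assoc, "n_controls")
  if (is.null(n_cases) || is.na(n_cases) || is.null(n_controls) ||
      is.na(n_controls) || n_cases <= 0 || n_controls <= 0)
    stop("need positive case/control counts")
  chisq <- assoc$STAT[!is.na(assoc$STAT)]^2
  if (length(chisq) < 100) stop("need at least 100 SNPs")
  lam <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  p <- sort(assoc$P[!is.na(assoc$P)])
  qq <- data.frame(expected = -log10(stats::ppoints(length(p))),
                   observed = -log10(p))
  structure(list(lambda_observed = lam,
                 lambda_1000 = lambda_1000(lam, n_cases, n_controls),
                 median_chisq = stats::median(chisq),
                 n_cases = n_cases, n_controls = n_controls, qq = qq),
            class = "inflation_summary")
}

#' @export
print.inflation_summary <- function(x, ...) {
  cat(sprintf("genomic inflation: lambda = %.4f, lambda_1000 = %.4f\n",
              x$lambda_observed, x$lambda_1000))
  cat(sprintf("  median chi2 = %.4f; %d cases / %d controls\n",
              x$median_chisq, x$n_cases, x$n_controls))
  invisible(x)
}

#' Greedy LD clumping of genome-wide significant SNPs into independent loci
#'
#' Significant SNPs are sorted by ascending p-value (ties broken by
#' chromosome, position, then id); the top unassigned SNP becomes a lead and
#' every significant SNP on the same chromosome within \code{window_bp} and
#' with squared genotype correlation at least \code{clump_r2} joins its locus.
#' The output is invariant to the input row order.
#'
#' @param assoc an association table.
#' @param panel the genotype_panel the scan was run on (for r2).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param clump_r2 r2 threshold for locus membership (default 0.1).
#' @param window_bp clumping window (default 1 Mb).
#' @return data.frame (class "locus_table"): locus, CHR, BP, SNP, A1, P, BETA,
#'   STAT, NMISS and a list column \code{members}.
#' @export
clump_loci <- function(assoc, panel, p_threshold = 5e-8, clump_r2 = 0.1,
                       window_bp = 1e6) {
  sig <- assoc[!is.na(assoc$P) & assoc$P < p_threshold, , drop = FALSE]
  empty <- data.frame(locus = integer(0), CHR = integer(0), BP = integer(0),
                      SNP = character(0), A1 = character(0), P = numeric(0),
                      BETA = numeric(0), STAT = numeric(0), NMISS = integer(0))
  empty$members <- list()
  class(empty) <- c("locus_table", "data.frame")
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$P, sig$CHR, sig$BP, sig$SNP), , drop = FALSE]
  col <- match(sig$SNP, panel$variants$SNP)
  if (anyNA(col)) stop("association table and panel SNP ids disagree")
  assigned <- rep(FALSE, nrow(sig))
  rows <- list()
  locus <- 0L
  for (i in seq_len(nrow(sig))) {
    if (assigned[i]) next
    locus <- locus + 1L
    cand <- which(!assigned & sig$CHR == sig$CHR[i] &
                    abs(sig$BP - sig$BP[i]) <= window_bp)
    g_lead <- as.numeric(panel$dosage[, col[i]])
    members <- sig$SNP[i]
    for (j in setdiff(cand, i)) {
      r <- suppressWarnings(
        stats::cor(g_lead, as.numeric(panel$dosage[, col[j]]),
                   use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= clump_r2) {
        assigned[j] <- TRUE
        members <- c(members, sig$SNP[j])
      }
    }
    assigned[i] <- TRUE
    row <- sig[i, c("CHR", "BP", "SNP", "A1", "P", "BETA", "STAT", "NMISS")]
    row$locus <- locus
    row$members <- list(members)
    rows[[locus]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[, c("locus", "CHR", "BP", "SNP", "A1", "P", "BETA", "STAT",
                 "NMISS", "members")]
  rownames(out) <- NULL
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Fixed-effect meta-analysis of per-SNP association tables
#'
#' Combines single-trait scans SNP by SNP. Alleles are harmonized to the
#' first table: where A1/A2 are swapped the beta sign is flipped;
#' irreconcilable allele pairs are dropped with a log entry. The default
#' combination is inverse-variance weighting (BETA_meta = sum(w b)/sum(w),
#' w = 1/SE^2, SE_meta = sum(w)^-0.5, P from the normal); "stouffer" combines
#' sample-size-weighted z-scores instead.
#'
#' @param tables list of association tables sharing a SNP id space.
#' @param method "ivw" (default) or "stouffer".
#' @return an association_table of combined results.
#' @export
meta_analyse_gwas <- function(tables, method = c("ivw", "stouffer")) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  ref <- tables[[1]]
  beta_mat <- matrix(NA_real_, nrow(ref), length(tables))
  se_mat <- beta_mat
  n_mat <- beta_mat
  dropped <- character(0)
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    i <- match(ref$SNP, tb$SNP)
    same <- tb$A1[i] == ref$A1 & tb$A2[i] == ref$A2
    swap <- tb$A1[i] == ref$A2 & tb$A2[i] == ref$A1
    bad <- !is.na(i) & !(same | swap)
    dropped <- union(dropped, ref$SNP[bad])
    b <- ifelse(swap, -tb$BETA[i], tb$BETA[i])
    b[bad] <- NA
    beta_mat[, k] <- b
    se_mat[, k] <- ifelse(bad, NA, tb$SE[i])
    n_mat[, k] <- ifelse(bad, NA, tb$NMISS[i])
  }
  w <- 1 / se_mat^2
  if (method == "ivw") {
    sw <- rowSums(w, na.rm = TRUE)
    beta <- rowSums(w * beta_mat, na.rm = TRUE) / sw
    se <- 1 / sqrt(sw)
    stat <- beta / se
  } else {
    z <- beta_mat / se_mat
    wn <- sqrt(n_mat)
    stat <- rowSums(wn * z, na.rm = TRUE) / sqrt(rowSums(wn^2, na.rm = TRUE))
    sw <- rowSums(w, na.rm = TRUE)
    beta <- rowSums(w * beta_mat, na.rm = TRUE) / sw
    se <- 1 / sqrt(sw)
  }
  keep <- rowSums(!is.na(beta_mat)) > 0
  out <- data.frame(CHR = ref$CHR, BP = ref$BP, SNP = ref$SNP, A1 = ref$A1,
                    A2 = ref$A2, P = p_from_z(stat), BETA = beta, SE = se,
                    STAT = stat, NMISS = rowSums(n_mat, na.rm = TRUE),
                    stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  attr(out, "model") <- paste0("meta-", method)
  attr(out, "dropped") <- dropped
  out
}

#' Convert an association scan to (SNP, A1, A2, N, Z) summary statistics
#'
#' @param assoc an association table.
#' @return data.frame with SNP, A1, A2, N and signed Z.
#' @export
assoc_to_sumstats <- function(assoc) {
  data.frame(SNP = assoc$SNP, A1 = assoc$A1, A2 = assoc$A2, N = assoc$NMISS,
             Z = assoc$STAT, stringsAsFactors = FALSE)
}
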