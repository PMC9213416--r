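#' Write a genotype panel as PLINK BED/BIM/FAM
#'
#' Variant-major BED with the standard magic bytes; BIM holds 1-based
#' positions with allele 1 as the counted (effect) allele; FAM uses the sample
#' id for both family and individual id, sex coded 1 = male, 2 = female.
#'
#' @param panel a genotype_panel.
#' @param prefix output path prefix (files prefix.bed/.bim/.fam are written).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  v <- panel$variants
  fam <- data.frame(FID = panel$sample_ids, IID = panel$sample_ids,
                    PID = 0L, MID = 0L,
                    SEX = ifelse(panel$sex == "male", 1L, 2L), PHENO = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(CHR = v$CHR, SNP = v$SNP, CM = 0, BP = v$BP,
                    A1 = v$A1, A2 = v$A2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  # 2-bit codes per sample: 00 = hom A1 (dosage 2), 10 = het, 11 = hom A2,
  # 01 = missing; packed 4 samples per byte, low bits first.
  codes <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  n_bytes <- ceiling(n / 4)
  for (j in seq_len(nrow(v))) {
    x <- panel$dosage[, j]
    cd <- ifelse(is.na(x), 1L, codes[as.character(x)])
    cd <- c(cd, integer(n_bytes * 4 - n))
    dim(cd) <- c(4, n_bytes)
    byte <- cd[1, ] + cd[2, ] * 4L + cd[3, ] * 16L + cd[4, ] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read a PLINK BED/BIM/FAM fileset into a genotype panel
#'
#' @param prefix path prefix of the fileset.
#' @return a genotype_panel (MAF recomputed from dosages; INFO set to 1).
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(bim) <- c("CHR", "SNP", "CM", "BP", "A1", "A2")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a variant-major PLINK BED file")
  body <- as.integer(raw[-(1:3)])
  n_bytes <- ceiling(n / 4)
  # unpack all 2-bit fields at once
  q <- rbind(body %% 4L, (body %/% 4L) %% 4L, (body %/% 16L) %% 4L,
             body %/% 64L)
  dim(q) <- c(4L * n_bytes, m)
  q <- q[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, m)
  dosage[q == 0L] <- 2L
  dosage[q == 2L] <- 1L
  dosage[q == 3L] <- 0L
  p <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(
    sample_ids = as.character(fam$V2),
    sex = ifelse(fam$V5 == 1L, "male", "female"),
    variants = data.frame(CHR = bim$CHR, BP = bim$BP, SNP = bim$SNP,
                          A1 = bim$A1, A2 = bim$A2, maf = p, info = 1,
                          stringsAsFactors = FALSE),
    dosage = dosage
  ), class = "genotype_panel")
}

#' Write phenotype/covariate tables in PLINK --pheno/--covar layout
#'
#' FID and IID columns (both the sample id) followed by the requested columns;
#' missing values written as "NA".
#'
#' @param data data.frame with a \code{sample_id} column.
#' @param path output file.
#' @param columns columns to write after FID/IID (default: all but sample_id).
#' @return the path, invisibly.
#' @export
write_pheno <- function(data, path, columns = NULL) {
  columns <- columns %||% setdiff(names(data), "sample_id")
  out <- cbind(data.frame(FID = data$sample_id, IID = data$sample_id),
               data[, columns, drop = FALSE])
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a PLINK-layout phenotype/covariate table
#'
#' @param path file written by [write_pheno()] (or PLINK).
#' @return data.frame with a \code{sample_id} column (from IID).
#' @export
read_pheno <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = "NA")
  d$sample_id <- as.character(d$IID)
  d[, c("sample_id", setdiff(names(d), c("FID", "IID", "sample_id")))]
}

#' Write a GRM in GCTA binary triple format
#'
#' Writes prefix.grm.bin (lower triangle including the diagonal, row by row,
#' single precision), prefix.grm.N.bin (number of SNPs per pair, single
#' precision) and prefix.grm.id (FID, IID).
#'
#' @param grm a [compute_grm()] object.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$sample_ids)
  lower <- grm$A[upper.tri(grm$A, diag = TRUE)]
  # upper.tri by column == lower triangle row by row for a symmetric matrix
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4); close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$M), length(lower)), con, size = 4); close(con)
  utils::write.table(data.frame(grm$sample_ids, grm$sample_ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read a GRM in GCTA binary triple format
#'
#' @param prefix path prefix of the .grm.bin/.grm.N.bin/.grm.id triple.
#' @return a grm object.
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  k <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = k, size = 4)
  Ns <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = k, size = 4)
  A <- matrix(0, n, n)
  A[upper.tri(A, diag = TRUE)] <- vals
  A <- A + t(A) - diag(diag(A))
  structure(list(sample_ids = as.character(ids), A = A,
                 M = as.integer(round(Ns[1]))), class = "grm")
}

#' Write an association table with the standard eight-column header
#'
#' Columns CHR, BP, SNP, A1, P, BETA, STAT, NMISS plus SE, tab separated.
#'
#' @param assoc an association table from [association_scan()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_assoc <- function(assoc, path) {
  utils::write.table(
    assoc[, c("CHR", "BP", "SNP", "A1", "P", "BETA", "STAT", "NMISS", "SE")],
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write summary statistics in (SNP, A1, A2, N, Z) layout
#'
#' @param ss a summary-statistics data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  utils::write.table(ss[, c("SNP", "A1", "A2", "N", "Z")], path,
                     quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read summary statistics written by [write_sumstats()]
#' @param path input file.
#' @return data.frame with SNP, A1, A2, N, Z.
#' @export
read_sumstats <- function(path)
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)

#' Write LD scores in the .l2.ldscore dialect plus an M-count sidecar
#'
#' @param ldscores data.frame with CHR, SNP, BP, L2.
#' @param prefix output prefix; writes prefix.l2.ldscore and prefix.l2.M.
#' @return the prefix, invisibly.
#' @export
write_ldscore <- function(ldscores, prefix) {
  utils::write.table(ldscores[, c("CHR", "SNP", "BP", "L2")],
                     paste0(prefix, ".l2.ldscore"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  writeLines(as.character(nrow(ldscores)), paste0(prefix, ".l2.M"))
  invisible(prefix)
}

#' Read LD scores written by [write_ldscore()]
#' @param prefix input prefix.
#' @return data.frame with CHR, SNP, BP, L2 and attribute "M".
#' @export
read_ldscore <- function(prefix) {
  d <- utils::read.table(paste0(prefix, ".l2.ldscore"), header = TRUE,
                         stringsAsFactors = FALSE)
  attr(d, "M") <- as.numeric(readLines(paste0(prefix, ".l2.M"))[1])
  d
}
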