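#' Derive a named random substream seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Each stage
#' (genotype simulation, phenotype simulation, relatedness pruning, sample
#' splitting, ...) draws its own deterministic substream seed so stages can be
#' rerun independently without disturbing one another.
#'
#' @param master_seed integer master seed.
#' @param stream character label of the substream (e.g. "panel", "phenotypes").
#' @return an integer seed below 2^31 suitable for [set.seed()].
#' @export
substream_seed <- function(master_seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 31 + k) %% 1013904223
  as.integer((abs(as.numeric(master_seed)) * 69069 + h * 362437 + 1) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Two-sided normal p-value for a Wald statistic
#'
#' @param z Wald z statistic(s).
#' @return two-sided tail probability 2*pnorm(-|z|).
#' @export
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

#' Percentage from a numerator/denominator count pair
#'
#' Small helper used throughout descriptive reports so that every printed
#' proportion is recomputed from its counts.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits rounding digits for the percentage (default 2).
#' @return rounded percentage.
#' @export
pct <- function(num, den, digits = 2) {
  stopifnot(den > 0)
  round(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("'%s' must be a single value in %s", name,
                        if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

# FNV-style hash of a configuration object; changes iff any field changes.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}
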