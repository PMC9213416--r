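# Shared fixture builders: all panels are generated in code at test time.

# small simulated panel with no disease/trait machinery attached
tiny_panel <- function(n = 150, m = 200, seed = 42, rho = 0, block = 20,
                       maf_range = c(0.05, 0.5), missing_rate = 0) {
  cfg <- sim_config(n, m, master_seed = seed, ld_rho = rho,
                    ld_block_length = block, maf_range = maf_range,
                    missing_rate = missing_rate,
                    subtype_specs = default_subtypes()[0, ],
                    trait_specs = default_traits()[0, ], gxe_spec = NULL)
  simulate_panel(cfg)
}

# hand-built panel from an explicit dosage matrix
manual_panel <- function(dosage, maf = NULL, chr = NULL, bp = NULL,
                         a1 = NULL, a2 = NULL, info = NULL, sex = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  structure(list(
    sample_ids = sprintf("s%03d", seq_len(n)),
    sex = sex %||% rep(c("female", "male"), length.out = n),
    variants = data.frame(
      CHR = chr %||% rep(1L, m),
      BP = bp %||% (seq_len(m) * 10000L),
      SNP = sprintf("m%04d", seq_len(m)),
      A1 = a1 %||% rep("A", m), A2 = a2 %||% rep("G", m),
      maf = maf %||% (colMeans(dosage, na.rm = TRUE) / 2),
      info = info %||% rep(1, m), stringsAsFactors = FALSE),
    dosage = dosage), class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GRM object from an explicit matrix (for pruning/PCA contract tests)
manual_grm <- function(A, M = 1000L) {
  structure(list(sample_ids = sprintf("s%03d", seq_len(nrow(A))), A = A,
                 M = M), class = "grm")
}
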