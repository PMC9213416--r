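#!/usr/bin/env Rscript
# 06: phenotypic correlations and leave-one-out genetic correlations.
#
# Pearson correlations (with Fisher-z tests) between the grouped phenotype
# and each quantitative trait, the calculated free oestradiol derived from
# the oestradiol-, SHBG- and albumin-like traits, and the leave-one-out
# grid: for each subtype, the genetic correlation between that subtype and
# the grouped phenotype excluding it, via cross-trait LD-score regression on
# the package's own scans.

library(grouph2)

panel <- read_plink("results/cohort/panel_qc")
ph <- read_pheno("results/cohort/phenotypes.txt")
pcs <- read_pheno("results/cohort/pcs.txt")
ph <- ph[match(panel$sample_ids, ph$sample_id), ]
pcs <- pcs[match(panel$sample_ids, pcs$sample_id), ]
y <- ph$grouped_status

# free oestradiol from the literal published formula (traits are z-scaled
# simulants, shifted positive to act as stand-in concentrations)
cfo <- free_estradiol(E2 = ph$oestradiol_like - min(ph$oestradiol_like),
                      SHBG = ph$shbg_like - min(ph$shbg_like),
                      albumin = ph$albumin_like - min(ph$albumin_like))
ph$cfo_like <- cfo$cFO

traits <- c("igf1_like", "oestradiol_like", "shbg_like", "albumin_like",
            "height_like", "cfo_like")
tab <- do.call(rbind, lapply(traits, function(tr) {
  pc <- phenotypic_correlation(ph[[tr]], y)
  data.frame(trait = tr, r_p = pc$r, se = pc$se_r, p = pc$p, n = pc$n)
}))
print(tab, digits = 3)
write.table(tab, "results/phenotypic_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# leave-one-out genetic correlation grid (subtype vs grouped-minus-subtype)
lds <- read_ldscore("results/cohort/panel")
covs <- cbind(age = ph$age, tdi = ph$tdi, as.matrix(pcs[, -1]))
subtypes <- c("breast_like", "prostate_like", "uterine_like", "ovarian_like",
              "thyroid_like")
grid <- loo_rg_grid(panel, ph[, subtypes], lds, covariates = covs)
print(grid, digits = 3)
write.table(grid, "results/loo_rg_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("non-estimable LOO cells:", sum(is.na(grid$rg)), "of", nrow(grid), "\n")
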