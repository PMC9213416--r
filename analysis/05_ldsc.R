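#!/usr/bin/env Rscript
# 05: LD-score regression heritability and GREML concordance.
#
# Computes in-sample LD scores with the adjusted r2 estimator, regresses the
# grouped-phenotype GWAS chi-squares on them, converts the slope to
# liability-scale h2 under K = P, and compares the estimate with the GREML
# result from stage 03.

library(grouph2)

panel <- read_plink("results/cohort/panel_qc")
ph <- read_pheno("results/cohort/phenotypes.txt")
ph <- ph[match(panel$sample_ids, ph$sample_id), ]
P <- mean(ph$grouped_status)

lds <- compute_ld_scores(panel)
write_ldscore(lds, "results/cohort/panel")
cat(sprintf("LD scores: mean %.2f, range [%.2f, %.2f]\n", mean(lds$L2),
            min(lds$L2), max(lds$L2)))

ss <- read_sumstats("results/gwas_grouped.sumstats.tsv")
fit <- ldsc_h2(ss, lds, M = nrow(lds), K = P, P = P)
print(fit)

greml <- read.table("results/heritability.tsv", header = TRUE, sep = "\t")
gl <- greml[greml$parameter == "h2_liability", ]
se_comb <- sqrt(gl$se^2 + fit$se_h2_liability^2)
cat(sprintf("GREML %.4f (%.4f) vs LDSC %.4f (%.4f): |diff| = %.4f = %.2f combined SE\n",
            gl$estimate, gl$se, fit$h2_liability, fit$se_h2_liability,
            abs(gl$estimate - fit$h2_liability),
            abs(gl$estimate - fit$h2_liability) / se_comb))

out <- data.frame(method = c("greml", "ldsc"),
                  h2_liability = c(gl$estimate, fit$h2_liability),
                  se = c(gl$se, fit$se_h2_liability),
                  intercept = c(NA, fit$intercept))
write.table(out, "results/h2_concordance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
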