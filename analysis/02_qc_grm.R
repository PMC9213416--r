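#!/usr/bin/env Rscript
# 02: quality control and genomic relationship matrix.
#
# Applies the QC cascade (call rate, INFO, MAF, HWE mid-p, ambiguous and
# duplicated variants), builds the frequency-standardized GRM, prunes one
# member of each pair with relatedness > 0.05, removes PC1/PC2 outliers
# beyond 6 SD and stores the leading PCs for use as covariates.

library(grouph2)

panel <- read_plink("results/cohort/panel")
vi <- read.table("results/cohort/variant_info.tsv", header = TRUE)
panel$variants$info <- vi$info[match(panel$variants$SNP, vi$SNP)]

qc <- apply_qc(panel, qc_thresholds())
cat("QC removals per rule:\n"); print(qc$report)
write.table(data.frame(rule = names(qc$report), removed = qc$report),
            "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
panel <- qc$panel

grm <- compute_grm(panel)
# the 0.05 threshold is raised to the GRM sampling-noise floor at this panel
# size; see relatedness_cutoff()
cutoff <- relatedness_cutoff(grm, 0.05)
cat(sprintf("relatedness cutoff: %.4f\n", cutoff))
kept <- prune_related(grm, cutoff, seed = substream_seed(2026L, "prune"))
cat("relatedness pruning removed", length(grm$sample_ids) - length(kept),
    "samples\n")
grm <- subset_grm(grm, kept)
pcf <- pc_outlier_filter(grm, n_pcs = 10, sd_limit = 6)
cat("PC outlier filter removed", length(pcf$removed), "samples\n")
grm <- subset_grm(grm, pcf$kept)

write_grm_gcta(grm, "results/cohort/grm")
write_plink(subset_panel(panel, samples = pcf$kept), "results/cohort/panel_qc")
pcs <- data.frame(sample_id = pcf$kept,
                  pcf$pcs[pcf$kept, , drop = FALSE])
write_pheno(pcs, "results/cohort/pcs.txt")
cat("GRM over", length(grm$sample_ids), "samples,", grm$M, "variants\n")
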