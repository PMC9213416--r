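Package: grouph2
Title: Liability-Scale Heritability and Genetic Correlation for Grouped Disease Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics toolkit for analysing several related binary
    disease subtypes as a single grouped phenotype. Provides a liability-threshold
    cohort simulator with block-LD genotypes and a shared polygenic factor,
    genotype/sample quality control and genomic-relationship-matrix construction,
    average-information REML variance-component estimation (univariate and
    bivariate) with observed-to-liability conversion, per-SNP association scans
    with genomic-inflation diagnostics and LD clumping, LD-score regression for
    heritability, genetic correlation and summary-statistic gene-environment
    interaction variance, phenotypic correlations with Fisher-z tests, free
    oestradiol calculation, leave-one-out grouping analyses, and a pipeline
    orchestrator with split-sample meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
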