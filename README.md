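# grouph2

SNP-based heritability, genetic correlation and gene–environment interaction
for **grouped disease phenotypes** — several related binary disease subtypes
analysed as a single trait on the liability scale.

The package is aimed at statistical geneticists who want the full
quantitative-genetics chain behind a grouped-cancer style analysis as
testable R code: when site-specific cancers (breast, prostate, uterine,
ovarian, thyroid) share hormonal aetiology, coding them as one disease can
reveal shared polygenic signal that per-site analyses are underpowered to
see. Because the real individual-level cohorts behind such analyses are
access-restricted, `grouph2` ships a first-class synthetic cohort generator
that reproduces the statistical structure the estimators assume, so every
stage is verifiable end to end on a desk machine.

## What it computes

* **Liability-threshold simulation** — block-LD genotype panels
  (Gaussian-copula AR(1) haplotypes, exact Hardy–Weinberg), sex-restricted
  disease subtypes loading on a shared polygenic factor, correlated
  quantitative traits, and environments that modulate SNP effects
  (`sim_config()`, `simulate_panel()`, `simulate_phenotypes()`).
* **QC and GRM** — the standard cascade (call rates, INFO, MAF, HWE exact
  mid-p, ambiguous/duplicate SNPs), the frequency-standardized genomic
  relationship matrix A with A_jk = (1/M) Σ (x_ij − 2p_i)(x_ik − 2p_i)/(2p_i(1−p_i)),
  relatedness pruning, PC-outlier removal, cross-release discordance
  filtering (`apply_qc()`, `compute_grm()`, `prune_related()`,
  `pc_outlier_filter()`, `discordance_filter()`).
* **GREML** — AI-REML with EM warm-up for y = Xb + a + ε,
  var(a) = A σ²_g; the observed↔liability transformation
  h²_l = h²_o · K²(1−K)²/(P(1−P)z²); bivariate genetic correlations with
  Wald and 2-df LRT tests; stratified GxE (r_g = 1 test across environment
  strata); split-sample inverse-variance + Fisher meta-analysis
  (`reml_fit()`, `observed_to_liability()`, `bivariate_reml()`,
  `gxe_stratified()`, `split_meta()`).
* **GWAS** — per-SNP logistic or linear-probability scans, genomic inflation
  λ = median(χ²)/0.4549364 with the λ₁₀₀₀ rescaling, greedy LD clumping into
  independent loci, fixed-effect meta-analysis with allele harmonization
  (`association_scan()`, `genomic_inflation()`, `clump_loci()`,
  `meta_analyse_gwas()`).
* **LD-score regression** — adjusted-r² LD scores, univariate h², cross-trait
  r_g robust to shared controls, and the GxEsum interaction-variance model
  E[χ²_j | ℓ_j] = Nσ²_g1/M·ℓ_j + 1 + 2(σ²_g1 + σ²_τ1)
  (`compute_ld_scores()`, `ldsc_h2()`, `ldsc_rg()`, `interaction_scan()`,
  `gxesum_fit()`).
* **Phenotypic layer** — Pearson/Fisher-z correlations, the calculated free
  oestradiol formula (plus a conventional mass-action alternative), and
  leave-one-out grouping grids (`phenotypic_correlation()`,
  `free_estradiol()`, `loo_groupings()`, `loo_rg_grid()`).
* **Orchestration** — `run_pipeline()` drives simulate → QC → GRM → GREML →
  GWAS → LDSC → correlations with deterministic seeding; the numbered
  scripts under `analysis/` are the narrative workflow and write their
  tables under `results/`.

I/O uses the field's open formats: PLINK BED/BIM/FAM, PLINK-layout
phenotype/covariate tables, GCTA binary GRMs, `.l2.ldscore` tables and
(SNP, A1, A2, N, Z) summary statistics.

## Worked example

```r
library(grouph2)

cfg <- sim_config(n_samples = 2000, n_variants = 6000, master_seed = 42,
                  ld_rho = 0.9, ld_block_length = 25)
panel  <- simulate_panel(cfg)
cohort <- simulate_phenotypes(panel, cfg)
print(cohort)
#> cohort_phenotypes: 2000 samples, 5 subtypes
#>   grouped cases: 112 (5.60%)

grm <- compute_grm(apply_qc(panel)$panel)
y   <- cohort$data$grouped_status
fit <- observed_to_liability(reml_fit(y, grm), K = mean(y))
print(fit)
#> GREML heritability estimate
#>   sigma2_g = 0.0034 (0.0018), sigma2_e = 0.0495 (0.0023)
#>   h2 (observed scale) = 0.0650 (se 0.0330), p = 0.0487
#>   h2 (liability scale) = 0.2700 (se 0.1370), K = 0.0560
#>   logL = 1936.969 after 7 iterations (converged: TRUE); n = 2000

assoc <- association_scan(panel, y)
print(genomic_inflation(assoc))
#> genomic inflation: lambda = 1.1052, lambda_1000 = 1.4975
#>   median chi2 = 0.5028; 112 cases / 1888 controls
```

Reading the output: 5.6% of the simulated cohort are grouped cases; the
observed-scale variance ratio 0.065 converts, at K = P = 0.056, to a
liability-scale h² of 0.27 with a wide standard error (0.14) — binary traits
at 6% prevalence need far larger cohorts for tight intervals, which is why
the real analyses run at biobank scale (the generative liability h² here is
about 0.1, within one SE of the estimate). λ is slightly above 1 because the
phenotype genuinely is polygenic, and λ₁₀₀₀ amplifies (λ − 1) when rescaling
from 112 cases to a nominal 1000/1000 design. A quantitative trait at the
same scale is much better behaved:

```r
tr <- simulate_trait(panel, h2 = 0.4, seed = 7)
print(reml_fit(tr$y, grm))
#> GREML heritability estimate
#>   sigma2_g = 0.3618 (0.0452), sigma2_e = 0.6374 (0.0379)
#>   h2 (observed scale) = 0.3621 (se 0.0396), p = 5.52e-20
#>   logL = -945.109 after 6 iterations (converged: TRUE); n = 2000
```

The full narrative analysis lives in `analysis/01_simulate.R` …
`analysis/07_gxe.R`; run them in order from the repository root and each
writes its tables under `results/`.

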