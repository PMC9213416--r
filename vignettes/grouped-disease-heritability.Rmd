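---
title: "Liability-scale heritability and genetic correlation for grouped disease phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-scale heritability and genetic correlation for grouped disease phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grouph2)
```

## The scientific problem

Several clinically distinct cancers — breast, prostate, uterine, ovarian and
thyroid — share hormonal carcinogenesis pathways, which motivates analysing
them as a *single grouped disease* rather than site by site. The quantitative-
genetics questions that follow are: how much of the variance in liability to
the grouped disease is captured by common SNPs (SNP-based heritability, h²);
which loci drive the shared signal (GWAS of the grouped phenotype); how the
grouped phenotype relates genetically to endocrine and anthropometric traits
(bivariate genetic correlation, r_g); whether each subtype shares signal with
the group formed by the others (leave-one-out analysis); and whether the
genetic effects are modulated by environments such as adiposity
(gene–environment interaction).

`grouph2` implements this entire analysis chain — liability-threshold cohort
simulation, QC and GRM construction, AI-REML variance components with the
observed-to-liability transformation, association scans with inflation
diagnostics and LD clumping, LD-score regression (univariate, bivariate, and
the interaction-variance extension), phenotypic correlations, leave-one-out
grouping, and split-sample meta-analysis — as testable R functions over a
synthetic cohort generator, because the real individual-level data (a
biobank-scale cohort) is access-restricted.

## The model

### Liability threshold and GREML

A binary disease status y is modelled through a latent Gaussian liability
l = g + c + e, where g is an additive polygenic value, c a covariate
contribution and e a residual; an individual is a case when l exceeds the
threshold Φ⁻¹(1 − K) for lifetime prevalence K. Variance components are
estimated from the linear mixed model

  y = X b + a + ε,  var(a) = A σ²_g,  var(ε) = I σ²_e,

where A is the genomic relationship matrix
A_jk = (1/M) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2 p_i (1 − p_i)). Restricted
maximum likelihood is maximised with two EM warm-up iterations followed by
average-information (AI) updates with step-halving, converged when the
log-likelihood moves by less than 1e-6 (`reml_fit()`). Binary phenotypes are
analysed on the 0/1 observed scale and transformed to the liability scale with
the threshold-model factor K²(1−K)²/(P(1−P)z²) (`observed_to_liability()`),
which reduces to K(1−K)/z² under the convention K = P used throughout (the
cohort is treated as population-representative, so the sample case proportion
stands in for the lifetime prevalence; the limitation section returns to
this).

Computationally, the univariate model (and the bivariate model on a shared
sample set) is fitted in the eigenbasis of A: after one symmetric
eigendecomposition the covariance is diagonal (or 2×2-block-diagonal), so
each REML iteration costs O(n p²) rather than O(n³). Disjoint-strata designs
(the stratified GxE model) have no such shortcut and use a dense AI-REML
engine.

### Bivariate models and the GxE test

For two traits the genetic covariance is structured by the same GRM;
r_g = σ_g12 / √(σ²_g1 σ²_g2). On a shared sample set the residual covariance
σ_e12 is estimable; for the stratified gene–environment design the phenotype
in the two environmental strata is treated as two traits on *disjoint*
samples, the cross-stratum block of the GRM carries the genetic covariance,
and there is no residual covariance term. Under no interaction the SNP
effects coincide across strata and r_g = 1, so a Wald test of r_g = 1 is the
GxE test (`gxe_stratified()`). A likelihood-ratio alternative compares the
bivariate model with both covariance parameters fixed at zero against the
full model on 2 degrees of freedom; it is exposed through
`bivariate_reml(lrt = TRUE)` while the Wald test is the default for the
r_g = 1 hypothesis, since the two-parameter constraint is meaningful only for
the no-covariance null.

### GWAS diagnostics

Per-SNP scans (`association_scan()`) support logistic regression (IRLS, 25
iterations, separation flagged) and a linear-probability-scale fit of the 0/1
status; both are provided because grouped-disease effect sizes are commonly
reported on the linear scale while the fitted model is described as
logistic. The genomic inflation factor is λ = median(χ²)/qchisq(0.5, 1), with
qchisq(0.5, 1) = 0.4549364, and is rescaled to a 1000-case/1000-control
equivalent by λ₁₀₀₀ = 1 + (λ−1)(1/n_cases + 1/n_controls)/(2/1000). Lead SNPs
are selected greedily by ascending p (ties by chromosome, position, id),
absorbing significant SNPs with r² ≥ 0.1 within 1 Mb — the conventional
clumping defaults, exposed as parameters since the original analysis states
only that independent loci were formed.

### LD-score regression and GxEsum

LD scores use the small-sample-adjusted estimator
r̃² = r² − (1 − r²)/(n − 2) summed over a 1 Mb window including the self term
(`compute_ld_scores()`). Heritability comes from the weighted regression of
χ² on ℓ (weights 1/max(ℓ, 1)), h² = slope·M/N̄, with a free intercept that
absorbs confounding; standard errors are delete-one-block jackknives over 200
contiguous SNP blocks (fewer on small panels, never below 2), and χ² outliers
above max(80, 0.001·N) are removed before fitting — the defaults inherited
from standard practice, all exposed. Cross-trait regression of Z_A·Z_B gives
the genetic covariance; its intercept absorbs sample overlap, which is what
makes the estimator usable when two case-control traits share controls.
The interaction extension models the per-SNP interaction-term χ² as
E[χ²_j | ℓ_j] = N σ²_g1/M · ℓ_j + 1 + 2(σ²_g1 + σ²_τ1), so the slope recovers
the GxE variance σ²_g1 and the intercept the residual-heterogeneity term
σ²_τ1 = (b₀ − 1)/2 − σ²_g1 (`gxesum_fit()`); an intercept below 1 yields a
negative σ²_τ1 and is flagged as a boundary rather than truncated.

### Endocrine calculations and meta-analysis

Free oestradiol is computed by literal evaluation of the published formula
cFO = (E₂ − N_total)/(N_SHBG − (E₂ + N_E2)) with N_E2 = 0.64×10⁹·albumin + 1
and N_SHBG = 5.55×10⁴·SHBG. That expression is dimensionally inconsistent
with the mass-action free-hormone literature (the denominator mixes bound and
total quantities), but no worked value or unit convention accompanies it, so
literal evaluation is the only faithful implementation; a clearly named
conventional quadratic (`free_estradiol_mass_action()`) is provided for
comparison and used nowhere by default.

Split-sample meta-analysis pools point estimates by fixed-effect
inverse-variance weighting and combines p-values with Fisher's
−2Σlog p ~ χ²_{2k}. Fisher's method is defined for p-values only; applying
it to the estimates themselves is not meaningful, so the pooled estimate is
deliberately inverse-variance weighted.

## The synthetic cohort generator

`sim_config()` + `simulate_panel()` + `simulate_phenotypes()` define the
study conditions every test runs under.

* **Genotypes.** Haplotypes are Gaussian-copula AR(1) processes within LD
  blocks: each haplotype allele at SNP j is 1 when its latent value falls
  below the p_j-quantile. This preserves Hardy–Weinberg exactly per SNP,
  gives geometric LD decay inside blocks with independence between blocks,
  and makes LD strength a single controllable parameter (`ld_rho`). MAFs are
  uniform on [0.05, 0.5] by default.
* **Disease subtypes.** Five subtypes mirror the grouped-cancer composition:
  breast-, uterine- and ovarian-like (female-only), prostate-like
  (male-only), thyroid-like (both sexes); the excluded sex is recorded
  missing, never control. Each liability is
  √h²(c_t·G₀ + √(1−c_t²)·G_t) + covariates + residual, standardized, so the
  shared factor G₀ makes pairwise subtype r_g equal c_t·c_t'. Default
  within-eligible-sex prevalences (4.5, 5.0, 1.2, 0.8, 0.5 per cent) put the
  grouped sample proportion near 6 per cent, the reference scenario, with
  liability h² between 0.08 and 0.12 so the grouped phenotype lands near the
  10 per cent scale of interest. No per-subtype population prevalences are
  published for the source cohort, so these are configuration values, chosen
  once.
* **Quantitative traits and GxE.** Endocrine/anthropometric-like traits have
  target h² and genetic correlation with G₀. The GxE trait is
  √σ²_g0·g₀ + E·√σ²_g1·g₁ + √σ²_τ1·E·ε₀ + ε with a standardized environment,
  the generative counterpart of the interaction-variance model (defaults
  σ²_g0 = 0.20, σ²_g1 = 0.05, σ²_τ1 = 0).
* **Randomness.** One master seed; every stage (panel, phenotypes, pruning,
  splitting) derives a named substream (`substream_seed()`), so stages are
  independently rerunnable and byte-reproducible.
* **Incident/prevalent flags** are Bernoulli thinning of cases at rate 0.463
  (the incident fraction of the reference cohort); calendar-time diagnosis is
  not modelled.

What the generator deliberately does **not** emulate: realistic human LD maps
and MAF-dependent architecture (effects are i.i.d. normal on standardized
genotypes, the GREML working model), X-chromosome dosages, imputation error
(INFO scores are simulated attributes consumed by QC, not generated by an
imputation model), age-dependent hazards, and population structure beyond a
single homogeneous population (structure appears only in planted-outlier
tests). Passing tests therefore certify the estimators under their own
working model, not robustness to the full messiness of biobank data.

## Numerical choices

* Variance components are floored at 1e-6·var(y); boundary hits are flagged,
  and a trait whose genetic variance sits on the floor makes r_g "not
  estimable" (reported with the reason, mirroring how small-case-count
  cancers behave in summary-statistic regression).
* REML convergence |ΔlogL| < 1e-6, at most 100 iterations; non-convergence
  returns the last iterate flagged.
* An exact duplicate pair of traits puts the bivariate covariance on the
  positive-definite boundary; it is detected (|cor| > 1 − 1e-12) and returned
  as r_g = 1 with a boundary note instead of letting the optimizer stall.
* |r_g| > 1 estimates are clamped to ±1 with the raw value retained
  (`rg_raw`) and the clamp logged; Wald tests use the raw value.
* HWE uses the exact conditional distribution of heterozygote counts with the
  mid-p convention; the chi-square approximation misbehaves exactly where the
  filter matters (rare genotypes).
* QC filter order is fixed and logged: sample call rate, SNP call rate, INFO,
  MAF, HWE, ambiguous/duplicate removal — the original publication does not
  state an order, so this one is a documented package choice, and the cascade
  is idempotent.
* Relatedness pruning removes a seeded-random member of each offending pair,
  greedily from the largest relatedness down, and verifies post hoc that no
  retained pair exceeds the cutoff. At desk scale the production cutoff
  (0.05) can sit *below* the GRM's sampling-noise floor (≈ 1/√m_eff), where
  literal thresholding would discard most of an unrelated cohort;
  `relatedness_cutoff()` therefore raises the cutoff to 6 SD of the observed
  off-diagonal noise when that floor is higher. The pruning function itself
  keeps the nominal 0.05 default.
* Principal components come from the eigendecomposition of the (pruned) GRM
  — one source of truth at desk scale — rather than a separate thinned-SNP
  PCA.
* Missing dosages are mean-imputed for GRM/PCA/LD-score computation only;
  association testing uses observed genotypes, so NMISS varies per SNP.

## Problem sizes in the test suite

The validation suite is sized for a single CPU. Quantitative GREML recovery
runs 20 replicates at n = 3000, m = 8000 (four panels × five phenotype
draws, reusing each panel's eigendecomposition); the case-control
liability-scale recovery runs 10 replicates at n = 4000, K = P = 0.06, true
liability h² = 0.10. LDSC recovery and GREML concordance use one
n = 5000 × m = 20,000 block-LD panel, which also carries the GxEsum recovery
(σ²_g1 = 0.05). Bivariate r_g = 0.5 recovery uses ten replicates each for
GREML (n = 2000) and LDSC (n = 2000, m = 5000) plus one shared-controls
case-control design. The stratified-GxE type-I calibration runs 40 null
replicates at 500 samples per stratum (calibration does not improve with n),
with power against r_g = 0.15 checked at 1000 per stratum. Null calibration
(λ, interaction χ²) uses n = 2000, m = 20,000.

## Known limitations

* The K = P convention understates liability h² when the cohort under-samples
  cases relative to lifetime population risk, as volunteer cohorts do; the
  transformation accepts independent K and P for that reason.
* Linear mixed models on 0/1 phenotypes (the GREML route used throughout) are
  first-order approximations; logistic mixed models are out of scope.
* The LD-score weights are the simple 1/max(ℓ, 1) scheme, not the iterative
  heteroskedasticity-optimal weights; jackknife SEs absorb most of the
  difference at these scales.
* Partitioned (annotation-stratified) regression, dominance and
  multi-component GREML, mixed-model association and conditional analysis
  are not implemented.
* Sample sizes reachable on a desk machine leave wide standard errors for
  binary phenotypes at 6 per cent prevalence; single runs of the reference
  scenario are demonstrations of the machinery, while the replicated
  recovery tests are the package's evidence of correctness.
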