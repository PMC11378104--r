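# epimetab

DNA-methylation surrogates of ¹H-NMR metabolomic features, and their
evaluation as all-cause mortality predictors.

## The problem

Blood DNA methylation (Illumina-style beta values in [0,1]) and ¹H-NMR
metabolomics both predict age-related decline and mortality, and they carry
partly independent signal. A *DNAm surrogate* is a sparse linear model that
reconstructs a metabolomic feature (or a multi-analyte score such as a
MetaboHealth-style mortality score) from CpG beta values:

```
surrogate(x) = b0 + Σ_j w_j β_j          (w sparse over CpGs)
```

Training such surrogates across several population cohorts requires the
whole chain this package implements:

1. **Metabolomics QC** — per-cohort feature missingness filter, robust
   outlier flagging on the log scale (|z| > 5), removal of samples with > 1
   outlier, missing-aware NIPALS imputation, pooled log + z transform.
2. **Cross-cohort calibration** — sex-exact phenotype matching (age, BMI)
   against a reference cohort, then a per-feature affine map
   `x' = (x − μ_t)/σ_t · σ_r + μ_r` estimated on the matched subsets and
   applied to all samples, with k-NN batch-mixing and variance-component
   diagnostics.
3. **Surrogate training** — per-cohort EWAS (`feature ~ CpG`), pre-selection
   of CpGs with consistent slope sign and nominal p < 0.05 in both training
   cohorts, then elastic-net regression (α = 0.5) with the penalty tuned in
   the inner loop of a nested 5-fold cross-validation; reported accuracy
   (Pearson R, RMSE) comes from the outer folds.
4. **Mortality evaluation** — Cox proportional-hazards scans per SD of each
   surrogate (adjusted for age and sex, BH-corrected), C-index-driven
   stepwise forward/backward model composition, paired C-index comparison,
   time-dependent (IPCW) ROC/AUC, and Schoenfeld proportional-hazards
   checks.
5. **CpG characterization** — island/shore/shelf context, Fisher-exact
   enrichment against trait catalogues with BH correction, genes in cis
   (≤ 100 kb), cross-model overlap and recurrently selected CpGs.

Real multi-cohort compendia of this kind are access-restricted, so the
package includes a synthetic multi-cohort generator
(`simulate_dataset()`) with a ground-truth sidecar (causal CpG sets,
injected batch shifts, true log hazard ratios, generating R²) that makes
every stage testable end to end.

## Worked example

Three simulated cohorts; cohort B gets an injected batch effect (+0.5 mean,
×1.3 SD); `met_01` drives mortality with a true log-HR of 0.5 per SD. Train
a surrogate for `met_01` on cohorts A and B, project it onto held-out
cohort C, and scan it against survival:

```r
library(epimetab)
cfg <- simulation_config(
  cohort_specs = data.frame(name = c("A", "B", "C"), n = c(300, 300, 250),
                            age_mean = c(45, 49, 52), age_sd = c(10, 10, 10),
                            bmi_mean = c(25, 25.8, 26.4), bmi_sd = c(3.5, 3.5, 3.5),
                            male_fraction = c(0.5, 0.5, 0.45)),
  n_metabolites = 4, n_cpgs = 1500, causal_cpgs_per_metabolite = 100,
  cpg_effect_sd = 0.3 / sqrt(100), n_age_cpgs = 50, n_sex_cpgs = 50,
  hazard_coefs = c(0.5, 0, 0, 0),
  batch_shift = list(B = list(delta = 0.5, factor = 1.3)),
  seed = 1)
sim <- simulate_dataset(cfg)
res <- run_pipeline(sim$data, reference_cohort = "A",
                    train_cohorts = c("A", "B"), targets = "met_01",
                    training = training_config(n_lambda = 50, seed = 1))
res$surrogates$met_01$performance$folds
```

```
  fold         R      RMSE   n n_selected
1    1 0.5961076 0.7989791 120         31
2    2 0.5592967 0.9106903 120         32
3    3 0.5986276 0.7653449 120         29
4    4 0.5906768 0.8372529 120         21
5    5 0.5543312 0.7700425 120         29
```

Mean outer-fold R is 0.58 ("accurate" tier, R > 0.35): the surrogate
reconstructs about a third of the metabolite's variance from methylation
alone, in line with its generating R² of ≈ 0.5. The final model kept 37 of
39 pre-selected CpGs at λ = 0.0198. On the held-out cohort the projected
surrogate associates with mortality:

```r
res$scan[, c("score", "hr", "hr_lo", "hr_hi", "p", "p_adj")]
#>    score       hr    hr_lo    hr_hi           p       p_adj
#> 1 met_01 1.386694 1.085057 1.772184 0.008993762 0.008993762
```

A hazard ratio of 1.39 per SD (95% CI 1.09–1.77), adjusted for age and
sex — the surrogate carries the mortality signal its metabolite was given
(true HR per SD: e^0.5 ≈ 1.65, attenuated by reconstruction error).

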