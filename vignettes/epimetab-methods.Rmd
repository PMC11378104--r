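---
title: "Methylation surrogates of NMR metabolomics: models and design choices"
author: "epimetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation surrogates of NMR metabolomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epimetab)
```

## What this package does

Blood DNA methylation (450k-style beta values in [0,1]) and ¹H-NMR
metabolomics both carry mortality-relevant signal, and sparse linear models
can transfer the metabolomic signal onto the methylation platform. `epimetab`
implements that transfer as a tested pipeline: harmonize metabolite
concentrations across cohorts, train one elastic-net surrogate per metabolic
feature from CpG beta values under a nested cross-validation with
EWAS-guided pre-selection, project the surrogates onto held-out methylation
data, and evaluate them against all-cause mortality with Cox
proportional-hazards models, C-index-driven stepwise composition,
time-dependent ROC analysis and proportional-hazards diagnostics. A final
module characterizes the CpGs a model selects (island context, trait
catalogues, genes in cis, cross-model overlap).

Real multi-cohort methylation/metabolomics compendia are access-restricted,
so the package ships a synthetic multi-cohort generator with a complete
ground-truth sidecar. Every claim the test suite makes is a property of the
method verified against that ground truth, not a reproduction of any
cohort-specific estimate.

## The synthetic generator

`simulate_dataset()` draws, per cohort, age, BMI and sex from configurable
distributions, builds metabolite log-concentrations as a linear function of
centred age, sex and centred BMI plus Gaussian noise, and exponentiates, so
concentrations are positive and right-skewed and the downstream log
transform recovers Gaussian structure. Each metabolite owns a disjoint set
of causal CpGs whose logit-scale beta values load on the metabolite's pooled
z-score; separate CpG sets carry age and sex signal; all other CpGs are
noise. Betas are squashed through the inverse logit, hence always in [0,1].

The variance fraction of a metabolite recoverable from its causal CpGs has
the closed form `r2 = S/(1+S)` with `S = sum(w_jk^2)/sd_eps^2` on the
locally linear logit scale, and is reported in the ground-truth sidecar; an
OLS of the metabolite on its causal CpGs reproduces it within ±0.1 at
n = 2000 (tested). To emulate a generating R² of about 0.5 with k causal
CpGs, set the per-CpG weight SD to `sd_eps/sqrt(k)`.

Batch effects are injected per cohort and feature on the raw concentration
scale — an additive mean shift plus a multiplicative SD factor around the
cohort mean — because that is where real between-study calibration operates,
before any log transform. A strong negative shift can push the extreme low
tail of a concentration below zero; such cells are floored at half the
feature's smallest positive value, mimicking an assay detection limit.

Survival times invert the Weibull-baseline proportional-hazards survival
function `S(t|x) = exp(-(t/scale)^shape * exp(x'beta))` at uniform random
quantiles, with coefficients acting per SD of the (clean, pre-batch)
log-metabolites. Censoring is administrative and uniform on `[0, t_max]`,
with `t_max` solved numerically so the expected censored fraction
approximates the configured rate; the realised rate is approximate by
design. Defaults (shape 1.3, scale 40 years, 70% censoring) give event
curves typical of middle-aged population cohorts followed for one to two
decades.

What the generator does **not** emulate: the covariance structure of the
real Nightingale panel (features are conditionally independent given
phenotypes), family/twin structure, cell-type composition effects on
methylation, and probe-level artefacts. Passing tests therefore demonstrate
correctness and statistical calibration of the methods, not their field
performance on real cohorts.

## Metabolomics quality control

The QC chain runs in a fixed, idempotent order: feature panel filter →
outlier flagging → sample removal → NIPALS imputation → log + z. A feature
is dropped when its missing fraction in **any** cohort strictly exceeds the
threshold (default 0.3) — the generalization of dropping an analyte that is
80% missing in one study. Outliers are flagged per cell when the robust z
on the log scale, `|log x - median| / (1.4826 MAD)`, exceeds 5; the
threshold and the log-scale convention are configurable because published
pipelines rarely state them precisely. A sample is removed when it carries
strictly more than one flagged cell. Values at or below a detection limit
are kept by default (`set_missing` is available).

Imputation is a missing-aware NIPALS: scores and loadings are iterated with
inner products that skip missing cells, the matrix is **not** column-centred
(the mean structure is absorbed by the leading component), and only missing
cells are filled from the rank-k reconstruction, so observed values are
untouched and an exactly low-rank matrix is recovered exactly. Five
components, tolerance 1e-6 and 500 sweeps per component are the defaults;
non-convergence warns and returns the best estimate. The implementation is
cross-checked in the tests against an independent missing-aware NIPALS
(`mixOmics::impute.nipals`) and against a column-mean baseline it must beat.

## Cross-cohort calibration

The calibration assumes that phenotypically similar individuals should have
similar metabolomic profiles. For each non-reference cohort we build
sex-exact matched pairs against the reference by greedy nearest-neighbour
matching without replacement on (age, BMI) standardized by the reference
SDs, with a caliper of 0.5 SD units and ties broken by sample id, then
truncate to equal male and female pair counts by dropping the
worst-distance excess. Greedy matching keeps the procedure deterministic
and order-free; the caliper and replacement policy are package choices
(published descriptions name only the matching variables).

Per cohort and feature the map stores matched-subset means and SDs of
target and reference; `apply_calibration()` then maps **all** samples of
the cohort through `x' = (x - mu_t)/sd_t * sd_r + mu_r`. Because the map is
exactly affine, post-calibration matched-subset moments equal the reference
moments to machine precision (tested at 1e-10), and the transform is
monotone within each cohort-feature. Calibration is fitted and applied on
the raw concentration scale, before the final pooled log + z step.

Two diagnostics quantify residual batch structure. The k-NN batch-mixing
test compares, for randomly drawn samples, the cohort composition of the
k = 50 nearest Euclidean neighbours against the global composition with a
chi-square goodness-of-fit test and reports the fraction of neighbourhoods
rejected at 0.05; this is a deliberately simplified fixed-k variant of the
published kNN batch-effect test, used only as a mixing diagnostic. The
variance decomposition retains principal components up to 90% cumulative
variance, attributes each PC score to factors by single-factor regression
R² (categorical factors one-hot) with residual `1 - sum(R2)` clipped at
zero and renormalized, and averages with eigenvalue weights — a
fixed-effects approximation of principal variance component analysis, which
trades the random-effects machinery for transparency; overlapping factors
share credit.

## Surrogate training

For each target the EWAS regresses the (log + z) feature on each CpG's
betas separately within each training cohort — deliberately without
covariates, so potentially informative age/sex-correlated signal is not
discarded. A CpG is pre-selected iff its slope has the same sign in both
cohorts and both p values are below 0.05 (nominal, not
multiplicity-corrected: the pre-selection is a permissive filter, the
elastic net does the real selection).

The elastic net minimizes
`(1/2n)||y - b0 - Xb||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`
with `alpha` fixed at 0.5, by cyclic coordinate descent with active-set
iteration on internally standardized predictors (population 1/n variance),
tolerance 1e-7 on the largest standardized-coefficient update, warm starts
down a 100-point log-spaced grid from `lambda_max` (the smallest penalty
with an all-zero solution) to `lambda_max * 1e-4`. Coefficients are
returned on the original scale. The solver carries its own optimality
certificates: at `lambda = 0` with n > p it matches OLS to 1e-6, at
`lambda >= lambda_max` the solution is exactly null, and
`enet_kkt_residual()` verifies the Karush-Kuhn-Tucker conditions at any
grid point. The lasso special case is additionally cross-checked against
glmnet; the comparison is made at `alpha = 1` because glmnet's internal
response standardization rescales the quadratic half of the penalty when a
user lambda sequence is supplied, so elastic-net coefficients agree only up
to that reparametrization.

The nested cross-validation stratifies its 5 outer folds by cohort so each
fold preserves cohort proportions. Inside each outer-training set the
per-cohort EWAS, the pre-selection and the 5-fold inner CV over the lambda
grid (minimizing mean validation MSE, no one-standard-error rule) are all
recomputed, the model is refit at the best lambda and scored on the outer
fold (Pearson R, RMSE). Pre-selection is computed once per outer-training
set rather than inside every inner fold — the inner folds tune lambda
given that selection — with the stricter fully-nested variant available via
`preselect_in_inner_folds`; recomputing the EWAS 25 further times buys
little because the selection is a permissive filter, and the outer loop
remains a clean generalization estimate either way. The final model repeats
selection and tuning on all training data. An audit trail records the
sample ids used at every stage of every fold, and the tests assert
outer-test samples never reach the EWAS or the tuning.

Accuracy tiers summarize the mean outer-fold R: accurate above 0.35, mild
in (0.2, 0.35], low at or below 0.2. Published tier bands are stated
ambiguously at the boundaries; here both cut points are half-open with the
boundary value in the lower tier, and the choice is encoded in
`assign_tier()` and its tests. An optional variance pre-filter on beta SD
is off by default (no defensible published threshold).

## Score projection

`linear_score` objects carry weights, an intercept and a preprocessing spec
(log yes/no; z-scaling none / per dataset / pooled). Per-dataset z-scaling
is the classic meta-analysis mode that erases all between-cohort
differences; the pooled mode is meaningful after calibration and preserves
them — both are first-class because the contrast matters scientifically.
CpG-based models project as plain affine maps; CpGs absent from a beta
matrix fall back to a reference mean (the standard recourse when array
versions drop probes) and the imputation count is reported per model.
Models serialize to JSON with 17 significant digits, so a round trip
projects bit-identically. Published coefficient files (MetaboHealth,
clocks, EpiScores) are third-party artifacts consumed in this schema, not
bundled.

## Mortality models

Cox models are fitted by the `survival` package with the Efron tie
correction. Scores enter z-scaled within dataset, so hazard ratios are per
SD. The univariate scan fits one adjusted model per score (age + sex by
default), applies Benjamini-Hochberg across the scan, and records
per-feature failures without aborting. Harrell's C is computed by exhaustive
pair enumeration (compiled): a pair is usable iff the subject with the
earlier observed time is an event, equal-time pairs with both events are
unusable, and tied scores count one half.

The stepwise composition starts from the base covariates and alternates
forward additions (largest C gain, requiring gain > 0.001 and Wald
p < 0.05) with backward removals (p > 0.05 and C loss at most 0.001), for
at most 100 rounds with a cycling guard; the trace records every action
with C before/after and is exactly replayable. The thresholds are package
choices, exposed as arguments, formalizing a procedure usually described
only qualitatively. Removed variables may re-enter later.

Two models are compared by a paired t test on per-subject concordance
contributions (each subject's concordant-pair fraction), which accounts for
the correlation between models scored on the same samples; this follows the
spirit of the published C-index comparison test while approximating its
covariance estimator. The time-dependent AUC at a horizon is the
cumulative/dynamic IPCW estimator with Kaplan-Meier censoring weights
(cases weighted `1/G(t-)`, controls `1/G(horizon)`), which reduces exactly
to the binary AUC under zero censoring. Proportional hazards are tested per
covariate with the Grambsch-Therneau scaled-Schoenfeld score test on
KM-transformed time (`survival::cox.zph`); its empirical size and power are
verified by simulation in the acceptance suite.

## CpG characterization

Coordinates are 1-based positions; region intervals are 1-based half-open.
Island context follows the standard bands — island inside an interval,
shore within 2 kb of the nearest island edge, shelf within 2-4 kb, open sea
beyond — and partitions every CpG into exactly one class. Enrichment uses
the two-sided Fisher exact test over the selection vs. the remaining
universe, odds ratio `ad/bc` with the Haldane-Anscombe 0.5 correction when
a cell is zero, and BH across labels. Trait catalogues are filtered at load
time to Bonferroni-significant associations (`p < 0.05 / array size`,
array size configurable, 480,000 by default). Genes in cis are linked
within an inclusive 100 kb. Cross-model overlap is normalized by the
smaller selection (near-duplicate models score near 1; Jaccard is emitted
alongside), and recurrent CpGs require strictly more than the model-count
threshold, reporting majority-sign agreement and the median absolute-weight
rank as an importance summary (an explicit package definition — published
variable-importance figures rarely define theirs).

## Problem sizes and limitations

The test and acceptance suites run the full machinery at reduced but
structurally faithful sizes, chosen so the whole suite completes in minutes
on one CPU: 3 cohorts of 300-400 samples with 16 metabolites and 800 CpGs
for calibration properties; 2 cohorts of 750 samples, 4,000 CpGs and 200
causal CpGs per metabolite (generating R² ≈ 0.5) for surrogate training;
n = 1500-2000 with 50-200 replicates for the survival simulations. The CpG
universe size is a configuration choice, not a code constant; nothing in
the implementation depends on these sizes.

Known limitations: no DNAm probe-level QC (betas are assumed normalized);
no left truncation or competing risks in the survival module; the variance
decomposition and the batch-mixing diagnostic are simplified stand-ins for
their published namesakes; greedy matching is not optimal matching; and
synthetic results certify method behaviour, not performance on restricted
cohort data.
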