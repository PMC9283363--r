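---
title: "Methods: N-glycome preprocessing, association models and glycan-based discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: N-glycome preprocessing, association models and glycan-based discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dglyco)
```

## The analysis problem

`t1dglyco` analyses HILIC-UPLC chromatogram peak tables of plasma and IgG
N-glycans in family-based case-sibling cohorts of children at the onset of
type 1 diabetes. A sample is a vector of integrated peak areas (39 plasma
peaks GP1-GP39 or 24 IgG peaks GP1-GP24); the metadata carry family id,
sex, age, disease status, plate (batch), and optionally islet autoantibody
measurements (ZnT8R, ZnT8W, GAD, IA-2) with a per-assay limit of
quantification (LOQ). The package covers four stages:

1. **Preprocessing** -- total-area normalisation, log transform,
   empirical-Bayes batch correction, rank-based inverse normal
   transformation (RINT).
2. **Derived traits** -- sums of peak percentages sharing a structural
   feature (galactosylation, sialylation, bisecting GlcNAc, fucosylation,
   branching, high-mannose content).
3. **Association models** -- per-glycan linear and logistic models for
   sex/age, censored autoantibody levels, autoantibody counts and disease
   status, with Benjamini-Hochberg control.
4. **Discrimination** -- an elastic-net penalised mixed-effects logistic
   model with family-grouped cross-validation and a paired bootstrap AUC
   comparison of a glycan model against an age + sex null model.

A synthetic-cohort generator makes every stage testable without access to
registry data.

## The synthetic cohort generator

`simulate_cohort()` draws families with one affected proband and 0-5
unaffected siblings (default family-size distribution gives ~1.3 siblings
per proband, mirroring a registry-style sibling cohort of a few hundred
children). Log peak areas follow

$$\log a_{ij} = \mu_j + f_{F(i),j} + b_{B(i),j}
  + d_j\,\mathbb{1}[\text{affected}_i] + s_j\,\mathbb{1}[\text{male}_i]
  + g_j\,(\text{age}_i - \bar{\text{age}}) + \varepsilon_{ij},$$

with per-(family, peak) intercepts $f$, per-(batch, peak) shifts $b$ and
Gaussian residuals, all on the log scale. Three consequences drive the
design:

* The generative model is **multiplicative on areas**, so after total-area
  normalisation the data are compositional percentages, and the additive
  log-scale batch model is *exactly* the model the empirical-Bayes batch
  correction fits -- which makes the batch-correction checks sharp.
* Siblings share only per-peak family intercepts (no explicit genetic
  model). That is the minimal structure needed to exercise family-clustered
  inference and family-grouped cross-validation.
* Ages are uniform on 0.6-19.1 years (the span of a paediatric onset
  cohort); sexes are Bernoulli(0.5); plates are assigned round-robin.

Default noise scales (`family_intercept_sd = 0.3`, `batch_shift_sd = 0.2`,
`residual_sd = 0.3` on the log scale) give peak-level coefficients of
variation of roughly 30-50%, typical of across-child variation in UPLC
glycomics panels; the default baseline profile spans mean percentages of
about 0.3-6%, like a real chromatogram with a few dominant biantennary
peaks and many minor sialylated ones.

Autoantibody levels are latent log-normal variables with an **upper** LOQ:
the recorded level is $\min(c, \mathrm{LOQ})$ and the indicator $I$ is 1
when $c < \mathrm{LOQ}$ (quantified) and 0 at or beyond it. When an assay
designates a glycan peak, that peak's log value receives $+b_1 c$ below the
LOQ and the constant $+b_2$ beyond it -- the exact inverse of the
regression model the association stage fits. Because the full pipeline
(normalise, log, RINT) is nonlinear, routing this bump through the peak
table cannot reproduce $(b_0, b_1, b_2)$ exactly; the package therefore
also provides `simulate_censored_response()`, which draws directly from
the fitted equation and is what the parameter-recovery checks use. The
distributional parameters of the assays (log-normal with `meanlog = 0.5`,
`sdlog = 1`, LOQ at the latent 80th percentile, i.e. ~20% censored) are
package defaults exposed in the configuration: real assay distributions
and LOQ values are instrument-specific and must be supplied by the user.

`simulate_autoantibodies()` takes and returns the whole cohort object
rather than only the metadata, because wiring the censored effect into the
designated peak requires updating the peak table as well.

## Preprocessing choices

The stage order is fixed -- normalise, log, batch-correct, RINT -- and each
function refuses tables in the wrong state, so a table's provenance is
always explicit.

* **Normalisation** is to percentages summing to 100 (not proportions),
  the convention for chromatogram data.
* **Zeros before logging**: a zero percentage is replaced by half the
  smallest positive value of that peak column. Chromatogram peaks are
  rarely exactly zero, so this touches isolated cells; an `"error"` policy
  is available.
* **Batch correction** uses the parametric empirical-Bayes location/scale
  model via `sva::ComBat`, with no reference batch and no protected
  covariate matrix: correction happens before any modelling, and
  protecting disease status is a design choice we deliberately do not make
  by default. The risk is that a batch confounded with status would have
  real signal removed; users with confounded designs should randomise
  plates, as the generator does. A single batch returns the input
  unchanged with a warning. Note that EB shrinkage pulls each peak's batch
  correction toward the across-peak average, leaving a per-peak residual
  of the order of the sampling noise of the per-peak batch means; this is
  intentional (it is what makes ComBat robust for small batches) and is
  why batch-removal checks look at the average residual gap across peaks.
* **RINT** maps average ranks through $\Phi^{-1}((r - 0.5)/n)$ and then
  rescales to mean 0, SD 1 exactly. Ties receive average ranks
  deterministically; a random tie-break would destroy reproducibility.
  Constant vectors are rejected.

## Derived traits

`load_peak_annotation()` ships editable TSV panels assigning each peak the
structural features of its dominant glycan; peaks with co-eluting
structures carry the dominant structure (e.g. plasma GP12 is counted as
high-mannose M7 although an A2G2S1 isomer co-elutes). The shipped panels
are synthetic reconstructions consistent with the published structure
names for these chromatographic methods; laboratories with authoritative
peak assignments should replace them.

Each trait is the plain sum of member-peak percentages: G*k* sums complex
peaks with *k* galactoses, S*k* with *k* sialic acids, B the bisected
peaks, CF/AF core-/antennary-fucosylated peaks, LB/HB bi- vs
tri-/tetra-antennary peaks, HM the high-mannose peaks. No restricted
denominators are used, which keeps every trait linear in the percentages
(the mixture test exploits this) and in [0, 100]. The plasma panel yields
15 derivable traits, the IgG panel 9; galactosylation degrees plus HM
partition either panel, so those traits reconcile to 100 exactly.

## Association models

All models take rank-normalised glycan values, so effects are in SD units.

* **Sex x age group** (`fit_sex_age_model`): ordinary least squares on
  `glycan ~ sex * age_group`, estimated marginal means via `emmeans`, and
  pairwise t contrasts between age groups within sex and between sexes
  within age group (16 contrasts for 2 sexes x 4 groups), BH-adjusted.
  Pubertal age groups use sex-specific cut-offs (girls 6/11/15, boys
  6/13/17 years), configurable.
* **Censored autoantibody levels** (`fit_censored_autoantibody_model`):
  least squares on
  $\mathrm{glycan} = b_0 + I\,b_1\,c + (1 - I)\,b_2 + \mathrm{sex} +
  \mathrm{age}$ with $I = 1$ below the LOQ. The indicator convention is
  deliberately *upper*-tail -- a quantified level contributes through the
  slope $b_1$, levels beyond the LOQ contribute the constant offset
  $b_2$ -- because that is how an assay saturating at an upper limit
  behaves; `censor_side = "lower"` flips the convention for lower-LOQ
  assays. With no observations on one side the corresponding parameter is
  dropped with a warning. Note a subtlety exposed by the tests: under a
  joint shift of level and LOQ, $b_1$ and the beyond-LOQ fitted value
  $b_0 + b_2$ are invariant but $b_2$ alone is not.
* **Autoantibody counts** (`fit_autoantibody_count_model`): the count
  (1-4) enters as a numeric linear score adjusted for sex and age. One
  trend coefficient per glycan, matching the ordered-levels reading of the
  predictor.
* **Disease status** (`disease_association`): per glycan, logistic
  regression of status on the standardised glycan, age and sex with a
  family random intercept (lme4). When the variance estimate collapses to
  the boundary the model falls back to a glm with family-clustered robust
  standard errors (sandwich); under perfect separation a Firth-penalised
  fit is used and flagged. ORs are per 1 SD of glycan; BH is applied
  across the panel being tested (one family per panel x model, as in a
  per-table correction).

## The discriminative model

The full model is `status ~ age + sex + all glycan peaks` with a family
random intercept; the null model drops the glycans. Only directly measured
peaks (`GP<number>` columns) are allowed as predictors -- derived traits
are linear combinations of peaks and would be redundant (and are rejected
with an explicit message).

"Penalised mixed-model logistic elastic net" is not a single standard
estimator -- coordinate-descent elastic-net software has no random
effects -- so the package implements it as penalised quasi-likelihood with
an elastic-net penalty, and documents the construction:

* the minimised objective is
  $-\tfrac1n \sum_i \ell_i(\beta_0, \beta, u) +
  \lambda\left(\alpha\lVert\beta_{\mathrm{pen}}\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta_{\mathrm{pen}}\rVert_2^2\right) +
  \tfrac{1}{2n\sigma^2}\sum_f u_f^2$;
* an outer IRLS loop builds the weighted working least-squares problem;
  the inner loop is coordinate descent with soft-thresholding on the
  penalised coefficients (age and sex are never penalised) and a
  closed-form ridge update for the family intercepts; a step-halving line
  search on the exact objective makes the reported objective trace
  nonincreasing;
* the random-intercept SD is estimated by maximising the adaptive
  Gauss-Hermite (10-node) marginal likelihood in $\sigma$ with the fixed
  effects held at their current values, alternating with the coefficient
  updates. A boundary estimate ($\sigma < 0.0015$) is truncated to 0.
  `sigma = 0` reproduces a plain penalised logistic model for comparison
  with fixed-effects elastic-net software, which the tests exploit.

Defaults are $\alpha = 0.1$ and $\lambda = 10^{-4}$ -- at standardised
scale this is a near-unpenalised, ridge-leaning fit, and the tests verify
it coincides with unpenalised logistic regression when the penalty and
variance are switched off, and with glmnet at matching parameterisation.

**Cross-validation is grouped by family**: folds partition families, never
samples, because sibling correlation would otherwise leak across folds and
inflate the cross-validated AUC. Each held-out sample is scored with the
random intercept of its (unseen) family set to 0. Folds are not stratified
by outcome. **The bootstrap resamples families** (2000 replicates by
default) for the same reason; per replicate both AUCs are recomputed and
the two-sided p-value comes from the normal approximation to the bootstrap
distribution of the AUC difference, with a percentile CI. Replicates that
lose an outcome class are redrawn and counted. Sample-level resampling is
available via `resample = "sample"`.

AUC itself uses the Mann-Whitney identity with ties counted 1/2, verified
against exhaustive pair enumeration.

## Numerical choices and degenerate inputs

* Working weights in IRLS are floored at $10^{-6}$; coordinate descent
  stops when the largest within-sweep update falls below `inner_tol`
  (default $10^{-6}$), the outer loop below `tol` ($10^{-6}$).
* If no descent step is found after 25 halvings the optimiser declares
  numerical convergence rather than accepting an ascent.
* Perfect separation in the per-glycan logistic models is detected via
  non-convergence or runaway coefficients and handled with a
  Jeffreys-penalised (Firth) fit.
* Constant glycan vectors, single-class outcomes, empty design cells,
  single-level counts and sub-2-sample batches all raise early errors
  naming the offending unit.

## Problem sizes used by the checks

The replicate studies in the package's checks use cohorts of ~400 samples
(172 families) for calibration of the discriminative model, 50 replicates
per condition, 200 replicates at n = 300 for censored-model recovery, and
1000 random instances for the AUC oracle. These sizes were chosen to keep
each Monte-Carlo standard error a small fraction of the tolerance being
asserted while remaining comfortably runnable on a laptop.

## What passing tests do and do not show

The generator produces log-normal compositional data with exactly the
covariance structure the models assume (Gaussian family and batch effects,
homoscedastic residuals). Real chromatograms deviate: integration errors
correlate between adjacent peaks, batch effects can be
multiplicative-plus-drift rather than purely additive, family resemblance
has genetic structure beyond a shared intercept, and autoantibody
distributions are heavier-tailed than log-normal. Passing checks therefore
demonstrate internal correctness (the estimators recover the truth under
their own assumptions, at realistic sizes and noise levels), not that
those assumptions hold for any particular instrument or registry.

## Known limitations

* The exact construction of the original penalised mixed-model estimator
  this design emulates is not published; ours is one defensible
  construction, and the `sigma = 0` switch provides the fixed-effects
  alternative.
* PQL joint-mode estimates of fixed effects are mildly attenuated for
  binary outcomes with large cluster variance (a well-known property);
  the variance estimate itself uses adaptive quadrature and is close to
  unbiased. For the default near-zero penalty and CV-based evaluation this
  attenuation does not affect the ranking of predictions.
* Derived traits use plain sums over dominant structures; laboratories
  with authoritative co-elution tables should edit the shipped panels.
* No hyperparameter tuning is provided ($\alpha$, $\lambda$ are fixed by
  design); no calibration analysis of predicted probabilities.
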