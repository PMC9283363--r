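# t1dglyco

Plasma and IgG N-glycome analysis for family-based studies of type 1
diabetes onset.

Children newly diagnosed with type 1 diabetes show shifts in the
N-glycosylation of plasma proteins and IgG — more high-mannose and
bisecting-GlcNAc structures, less monogalactosylation, more IgG
disialylation — and those shifts carry enough signal to discriminate
affected children from their unaffected siblings. `t1dglyco` implements
the full statistical pipeline for such studies, starting from integrated
HILIC-UPLC chromatogram peak areas (39 plasma peaks GP1–GP39 or 24 IgG
peaks GP1–GP24 per sample):

1. **Preprocessing** — total-area normalisation to percentages,
   log transform, parametric empirical-Bayes batch correction (ComBat),
   rank-based inverse normal transformation
   \(x \mapsto \Phi^{-1}\!\big(\tfrac{r(x)-0.5}{n}\big)\), rescaled to
   mean 0 / SD 1.
2. **Derived glycosylation traits** — 15 plasma and 9 IgG traits as sums
   of peak percentages sharing a structural feature (G0–G4 galactosylation,
   S0–S4 sialylation, B bisecting GlcNAc, CF/AF core/antennary fucose,
   LB/HB branching, HM high-mannose), from editable packaged peak
   annotations.
3. **Association models** — per glycan: sex × pubertal-age-group GLM with
   emmeans post-hoc contrasts; a censored autoantibody model
   `glycan = b0 + I·b1·c + (1−I)·b2 + sex + age` with `I = 1` below the
   assay's limit of quantification; an autoantibody-count trend model
   (1–4 autoantibodies as a linear score); and family-clustered logistic
   disease models reporting ORs per SD of glycan, all with
   Benjamini–Hochberg control.
4. **Discrimination** — elastic-net penalised mixed-effects logistic
   regression (default α = 0.1, λ = 10⁻⁴; objective
   −n⁻¹∑ℓᵢ + λ(α‖β‖₁ + (1−α)‖β‖₂²/2) + ∑ᶠuᶠ²/(2nσ²), family random
   intercept estimated by adaptive Gauss–Hermite quadrature), evaluated by
   family-grouped 10-fold cross-validation, with a paired family-bootstrap
   comparison (2000 replicates) of the glycan model against an age + sex
   null model.

A synthetic sibling-pair cohort generator (`simulate_cohort()`) reproduces
the statistical structure the pipeline assumes — compositional peak
percentages with family-correlated effects, additive log-scale batch
shifts, sex/age/disease effect vectors, upper-LOQ-censored log-normal
autoantibody levels — so every stage is testable without registry data.

## Worked example

```r
library(t1dglyco)
library(dplyr)

# a synthetic cohort: 150 families, disease effects on 9 of 39 peaks
cfg <- sim_config(n_families = 150, seed = 42,
                  disease_effect = c(rep(0.35, 6), rep(-0.35, 3), rep(0, 30)))
cohort <- simulate_cohort(cfg)
#> <t1d_cohort> 357 samples / 150 families (150 affected, 207 unaffected), 39 peaks

pct <- preprocess_peaks(cohort$peak_table, cohort$metadata, until = "percent")
rn  <- preprocess_peaks(cohort$peak_table, cohort$metadata)  # rank-normal

compute_derived_traits(pct, "plasma") |> select(sample_id, G0:G4) |> head(3)
#>   sample_id    G0    G1    G2    G3    G4
#> 1 S00001    0.952  29.3  40.7  7.01 10.1
#> 2 S00002    1.28   19.7  44.8  6.06  8.86
#> 3 S00003    0.569  20.3  46.5  8.57  9.29

disease_association(rn, cohort$metadata) |> arrange(p) |> head(5)
#>   glycan    or ci_lo ci_hi        p        q
#> 1 GP7    0.285 0.214 0.381 1.62e-17 5.83e-16
#> 2 GP9    0.370 0.294 0.466 2.99e-17 5.83e-16
#> 3 GP5    2.59  2.07  3.24  6.33e-17 8.23e-16
#> 4 GP3    2.57  2.03  3.24  2.14e-15 2.08e-14
#> 5 GP8    0.354 0.272 0.460 9.27e-15 7.23e-14

disc <- run_full_vs_null(rn, cohort$metadata, seed = 1)
disc
#> <discrimination: full vs null>
#>   full  AUC = 0.932
#>   null  AUC = 0.468
#>   delta = 0.464, bootstrap p = 1.2e-56
autoplot(disc)   # overlaid out-of-fold ROC curves
```

The odds ratios are per 1 SD of the rank-normalised glycan, adjusted for
age and sex with a family random intercept, and BH-corrected across the
panel: the peaks simulated with positive log-scale disease effects come
out with OR > 1, the negative ones with OR < 1, and the null peaks are
non-significant. The full model's cross-validated AUC of 0.93 against the
chance-level null model reflects the strong simulated multi-peak signal.

End-to-end runs (simulate → preprocess → traits → associate →
discriminate, with a manifest and a markdown summary) are available
through `run_pipeline()` or the thin command-line wrapper in
`inst/cli/t1dglyco.R`.

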