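# amytraj

Longitudinal amyloid-PET trajectory modelling and slope-reduction trial
design for matched case–control cohorts.

## What it is for

Serial amyloid PET measures a participant's β-amyloid load as a
standardized uptake value ratio (SUVR) at baseline and again after an
interscan interval. Across a cohort spanning a range of baseline load, the
annualized change ΔSUVR/yr plotted against baseline SUVR forms an
inverted-U curve — accumulation accelerates at low load, peaks near SUVR
1.8 and decelerates towards saturation — and its integral over time is the
sigmoid level-versus-time trajectory of amyloid accumulation. `amytraj`
implements that analysis chain for biostatisticians working with two-visit
PET cohorts of dementia-with-Lewy-bodies-like cases and 4:1 matched
cognitively unimpaired controls:

* a **synthetic matched-cohort generator** built on the bounded logistic law
  `dA/dt = r (A − L)(U − A)` (so every stage is testable without patient
  data), with configurable group compositions, baseline-load distributions,
  interscan intervals and clinical-decline couplings;
* **greedy 4:1 matching** on sex and APOE ε4 (exact) and age (nearest,
  3-year caliper, without replacement);
* **annualization** of two-visit SUVR and clinical changes;
* the **rate curve**: a cubic P-spline of ΔSUVR/yr on baseline SUVR whose
  penalty weight is tuned by bisection so the smoother-matrix trace (the
  effective degrees of freedom) equals 4, with sandwich pointwise bands,
  plus nested-spline F tests for group shape differences, a vertical group
  shift, and nonlinearity;
* **trajectory integration**: fixed-step 4th-order Runge–Kutta on
  `dA/dt = max(f̂(A), 0)` with plateau and range stopping rules;
* an **association table**: unadjusted simple regressions of each clinical
  measure's annual change on baseline SUVR and on ΔSUVR/yr, and a
  randomized-block ANOVA for matched baseline comparisons;
* **trial sample sizes**: random-intercept/random-slope mixed models (REML)
  and the closed form
  `n/arm = 2 (z₁₋α + z₁₋β)² (σ²_slope + σ²_ε/Sxx) / (Δ·β₁)²`,
  jackknifed over subjects for means with asymptotic confidence intervals,
  over a 4 outcomes × 4 durations × 2 reductions grid.

## Worked example

```r
library(amytraj)

cfg    <- generator_config(seed = 1L)          # 35 cases, pool of 1000
cohort <- generate_cohort(cfg)
cases  <- subset(cohort$participants, group == "case")
pool   <- subset(cohort$participants, group == "control")
study  <- apply_matching(cohort, match_controls(cases, pool, ratio = 4, caliper = 3))
study
#> Synthetic matched-cohort data set
#>   participants: 175 (case: 35, control: 140)
#>   visits: 350 rows

ann <- annualize(study$visits)
fit <- fit_rate_spline(ann, group = "pooled", target_edf = 4)
fit
#> Penalized-spline rate curve (change in SUVR/yr vs baseline SUVR)
#>   group: pooled, n = 175, basis dim = 24
#>   lambda = 0.01119, effective df = 3.997 (target 4.00)
#>   x-range: [1.082, 2.391], residual SD = 0.02136 SUVR/yr
rate_curve_peak(fit)
#> [1] 1.745944
```

The curve peaks at baseline SUVR ≈ 1.75 — the generator's true rate law
peaks at 1.8, and a 175-person two-visit sample recovers it to within a
few hundredths. The group tests on the same cohort:

```r
test_shape_difference(ann)$p_value   # 0.10 — no group shape difference
test_vertical_shift(ann)$coefficient # -0.0063 SUVR/yr (SE 0.0043), p = 0.14
test_linearity(ann)$p_value          # 3.2e-07 — the inverted U is real
```

Integrating the fitted curve from the 2.5th percentile of baseline SUVR
gives the sigmoid accumulation trajectory:

```r
tr <- integrate_trajectory(fit, quantile(ann$baseline_suvr, 0.025), t_max = 30)
tr
#> Integrated amyloid trajectory (cumulative SUVR vs time)
#>   start level: 1.108 SUVR, 601 grid points, step 0.05 y
#>   final: 2.062 SUVR at 30.00 y (stop: reached_t_max)
```

Associations of clinical decline with amyloid load in the case arm, and
per-arm trial sizes from the same latent model:

```r
association_table(subset(ann, group == "case"))[1:2, ]
#>       predictor outcome coefficient    se      p r_squared
#> 1 baseline_suvr     drs      -13.72 6.630 0.0465    0.1148
#> 2 baseline_suvr cdr_sob        1.82 0.713 0.0154    0.1652

trial <- generate_trial_visits(cfg, 35, visit_times = c(0, 1, 1.5, 2))
sample_size_table(trial, outcomes = c("suvr", "cdr_sob"), follow_ups = c(12, 24))[1:2, ]
#>   outcome follow_up_months reduction_pct n_per_arm_mean ci_low ci_high
#> 1    suvr               12            25         194.99  90.26  299.73
#> 2    suvr               12            50          48.75  22.56   74.93
```

Detecting a 25% slowing of SUVR accumulation over 12 months needs ≈ 195
patients per arm under this cohort's variance components; halving the
detectable reduction to 50% divides n by exactly 4. `run_pipeline()`
executes all stages from one seed and writes every artifact plus an
MD5 manifest; a per-stage command-line wrapper ships in
`inst/cli/amytraj.R`.

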