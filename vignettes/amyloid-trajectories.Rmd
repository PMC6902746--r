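---
title: "Modelling longitudinal amyloid accumulation and trial sample sizes with amytraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal amyloid accumulation and trial sample sizes with amytraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Serial amyloid-PET studies measure a participant's fibrillar β-amyloid load
as a standardized uptake value ratio (SUVR) at a baseline visit and again
after an interscan interval of one to a few years. Across participants who
span a wide range of baseline load, the annualized change in SUVR plotted
against baseline SUVR forms an *inverted U*: accumulation accelerates at low
load, peaks mid-range (empirically near SUVR 1.8 for a composite cortical
region), and decelerates as the signal approaches saturation. Integrating
that rate-versus-level association over time yields the familiar *sigmoid*
level-versus-time trajectory of amyloid accumulation.

`amytraj` packages that analysis chain for a matched case–control design —
dementia-with-Lewy-bodies-like index cases with 4:1 age-, sex- and
APOE-ε4-matched cognitively unimpaired controls — together with the two
downstream stages such a study needs: unadjusted regressions of annualized
clinical decline on amyloid load, and mixed-model / jackknife per-arm sample
sizes for hypothetical slope-reduction trials. Because no patient-level data
ship with the package, a synthetic cohort generator with the same
statistical structure is a first-class, tested component: every stage can be
exercised, and every estimator validated against known truths, without any
download.

## The accumulation law

The generator's latent process is the bounded logistic law

$$\frac{dA}{dt} = r\,(A - L)(U - A),$$

where $A$ is the SUVR level, $L$ the amyloid-free floor, $U$ the saturation
ceiling, and $r$ a growth coefficient per (SUVR × year). Its closed form is
implemented in `logistic_level()`. The defaults $L = 1.1$, $U = 2.5$ and
$r = 0.112$ are calibration constants chosen so that the rate peaks at the
midpoint $(L+U)/2 = 1.8$ with a maximal rate $r(U-L)^2/4 \approx 0.055$
SUVR/year — the inverted-U and peak location reported by longitudinal PET
cohorts. The qualitative shape, not the particular constants, is the
scientifically meaningful content; all three are configurable.

## What the generator emulates — and what it does not

`generator_config()` holds every tunable with its default:

* **Cohort structure.** 35 index cases, a candidate control pool of 1000;
  88.6% men and 45.7% APOE-ε4 carriers in both groups. When
  `n × fraction` is an integer the composition is assigned exactly (31 men,
  16 carriers among 35 cases) rather than by independent coin flips, so
  tabulated counts are reproduced verbatim.
* **Baseline load.** Latent baseline SUVR is truncated-normal inside
  $(L, U)$, cases centred at 1.58 (SD 0.41) and controls at 1.36 (SD 0.22).
  The generator *moment-matches*: it solves for underlying normal parameters
  whose truncated moments equal the configured mean/SD, because truncating
  the configured parameters directly would bias the realized moments. The
  case SD 0.41 slightly exceeds what any truncated normal on (1.1, 2.5) can
  attain (the uniform-limit SD is ≈ 0.40), so the case group lands at the
  closest attainable spread (≈ 0.37) while the mean is matched exactly.
* **Ages and the control pool.** Case ages are N(69.6, 7.3). Control-pool
  ages emulate a registry's *pre-screened candidate list*: each candidate's
  age is drawn as the age of a random case in their own sex × APOE stratum
  plus a uniform ±4-year screening slop (`pool_age_jitter`). This mirrors
  how matched-cohort candidate lists are assembled in practice, and it is
  what makes full 4:1 matching within a 3-year caliper feasible from a pool
  of only 1000; with population-sampled ages the thin female strata make the
  matching infeasible in a nontrivial fraction of realizations.
* **Visits.** One baseline and one follow-up, the interval truncated-normal
  with group-specific means (1.2 y cases, 2.4 y controls, minimum 0.5 y) —
  hence the need for annualization. Observed SUVR adds independent N(0,
  `suvr_noise_sd`) measurement noise at each visit; within-person SUVR
  test–retest noise is not reported by reference cohorts, so its default
  0.02 is a stated guess and stays configurable.
* **Clinical decline.** Each of the 8 measures (DRS, CDR-SOB, MMSE,
  UPDRS-III, AVLT, BNT, TMT-A, RCF) declines linearly between visits with a
  per-subject annual slope
  `intercept + c_base · baseline SUVR + c_rate · ΔSUVR/yr + N(0, resid_sd)`.
  The `c_base`/`c_rate` defaults are the effect sizes observed for these
  scales in probable-DLB cohorts (e.g. DRS −22.40 per SUVR of baseline
  load, CDR-SOB +1.90, AVLT −25.05 per SUVR/yr of change); the intercepts
  are constants chosen so mean case slopes are clinically plausible (DRS
  ≈ −7/yr, CDR-SOB ≈ +1.8/yr at the typical case baseline), and residual
  SDs are set so the single-predictor $R^2$ values land near the observed
  ones. Both channels act simultaneously by default; since the latent rate
  is a deterministic function of baseline load, single-predictor
  regressions on the default cohort estimate confounded combinations, and
  validation of coefficient recovery therefore zeroes one channel at a
  time.
* **Not emulated.** Image acquisition and processing (the generator starts
  from composite SUVR), bounded/discrete score supports (scores are
  unbounded Gaussians — adequate for regression recovery, wrong in the
  extreme tails), practice effects, dropout, and diagnostic misclassification.
  Passing tests on this cohort show the *estimators* are correct, not that
  real data satisfy the generating assumptions.

Missing scores can be masked missing-at-random (`missing_prob`, default 0).
All randomness flows from one integer seed through per-stage substreams
(hash of the stage name), so stages rerun identically in isolation.

## The analysis core

**Annualization.** `annualize()` turns the two visits into per-year changes,
`(follow-up − baseline)/interval`, per measure; a value missing at either
visit propagates to a missing change, never zero. Intervals below 0.25 years
are refused (the quotient is numerically explosive).

**Rate curve.** `fit_rate_spline()` regresses annualized SUVR change on
baseline SUVR with a cubic B-spline basis (interior knots at predictor
quantiles, capped well below $n$) and a second-order *divided-difference*
penalty evaluated at the Greville abscissae. The divided-difference form —
rather than plain coefficient differences — makes the penalty null space
exactly the linear functions even with unequal knot spacing, so straight
lines are reproduced unshrunk at any penalty weight. "4 degrees of freedom"
is interpreted as the trace of the linear smoother matrix; the penalty
weight is found by bisection on $\log\lambda$ to hit the requested trace
within 0.005 (edf is strictly decreasing in $\lambda$, from the basis
dimension down to 2). All ridge algebra runs on the QR factorization of the
penalty-augmented design, which stays well conditioned at extreme weights
where normal equations fail. Pointwise 95% bands use the sandwich
covariance $\sigma^2 (B'B+\lambda P)^{-1} B'B\, (B'B+\lambda P)^{-1}$ with
$\sigma^2 = \mathrm{RSS}/(n-\mathrm{edf})$. Prediction outside the observed
baseline range is refused — the data carry no information there.

**Group comparisons.** Three tests accompany the curve, all on annualized
change versus baseline SUVR:

* `test_shape_difference()` — fixed-df natural cubic regression splines
  (4 df = 3 interior knots at quartiles) fitted pooled versus with a full
  group interaction; approximate F test from the analysis-of-deviance
  table. Fixed-df bases keep the models nested, which a penalized smooth
  would not.
* `test_vertical_shift()` — one common-shape penalized smooth (4 edf) plus
  an additive group indicator; the indicator is reported in SUVR/yr,
  positive when cases accumulate faster. The model's total edf is tuned to
  smooth + 1.
* `test_linearity()` — straight line versus the 4-df regression spline.

Matching enters the group comparison as the indicator model; block-level
random effects are deliberately out of scope. Baseline tables use
`compare_groups_blocked()`, the randomized-block two-way ANOVA
(`value ~ group + matching block`), with optional normalizing transforms —
log for baseline SUVR, square root for CDR-SOB, and the square root of the
reflected score for ceiling-effect scales like the MMSE. Which variable
gets which transform is an analyst's choice and is passed per call; the
pipeline applies the log transform to SUVR only, because the generator's
unbounded Gaussian scores need no normalization.

**Trajectory integration.** `integrate_trajectory()` treats the fitted
curve as the autonomous equation $dA/dt = \max(\hat f(A), 0)$ and runs
classical fixed-step 4th-order Runge–Kutta (default step 0.05 y). Negative
fitted rates are clipped *during integration only* — the cumulative curve is
a level process — while the displayed rate curve may go negative.
Integration stops at `t_max`, when the rate falls below `epsilon` (default
1e-4 SUVR/yr, a plateau), or when the level would exit the fitted range (no
extrapolation); the stop reason is recorded. The headline start level is the
2.5th percentile of observed baseline SUVR, configurable.

## Associations and the blocked baseline table

`fit_association()` / `association_table()` are unadjusted simple OLS
regressions of each measure's annualized change on baseline SUVR and on
SUVR change — 16 cells, complete cases, no multiplicity correction
(mirroring how such tables are conventionally reported). Covariate
adjustment is available behind the `adjust` argument but off by default.
The association table is a contract about *recovery of known synthetic
truths*, not about reproducing any particular published coefficients, which
would require the original cohort.

## Trial sample sizes

`fit_lmm()` fits the random-intercept/random-slope model
$y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})t_{ij} + \varepsilon_{ij}$
by REML (unstructured 2×2 random-effects covariance; exact-line data are
detected and returned directly, since REML is undefined at zero residual
variance). For a two-arm trial detecting a fraction $\Delta$ of the mean
slope with one-sided level $\alpha$ and power $1-\beta$ at visit times
$t_j$:

$$n_\text{per arm} =
  \frac{2\,(z_{1-\alpha} + z_{1-\beta})^2\,
        \left(\sigma^2_{slope} + \sigma^2_\varepsilon / S_{xx}\right)}
       {(\Delta\,\beta_1)^2},
  \qquad S_{xx} = \sum_j (t_j - \bar t)^2.$$

The normal (z) approximation matches the asymptotic-interval framing;
values are unrounded, with the ceiling applied only for display.
`jackknife_sample_size()` refits leave-one-subject-out and reports the mean
of the replicate sample sizes with SE $\sqrt{\frac{m-1}{m}\sum_i (n_i -
\bar n)^2}$ and a symmetric 95% interval; non-convergent refits are dropped
(more than 20% dropped is an error).

`sample_size_table()` evaluates the 4 outcomes × 4 durations × 2 reductions
grid. A duration resolves to the cumulative reading schedule {0, 12}, {0,
12, 18}, {0, 12, 18, 24}, {0, 12, 18, 24, 36} months. One mixed model per
outcome is fitted to the full assessment series and every duration is
evaluated through its schedule's $S_{xx}$ in the closed form: a per-duration
refit on the 12-month two-visit subset would be unidentifiable (three
variance parameters, two observations per subject), and the single-fit
reading is how such tables are produced in practice. Two structural
consequences follow analytically and are asserted by the tests: the
25%-versus-50% ratio is exactly 4 before rounding, and $n$ is nonincreasing
in duration. The hypothetical trial enrols the case-like arm only;
`generate_trial_visits()` draws it from the same latent model with
per-visit measurement noise (`clinical_visit_noise`). Dropout is not
modelled.

## Numerical and design choices

* Penalty-weight bisection: bracket $[10^{-12}, 10^{14}]$ on a log scale,
  tolerance 0.005 edf, 200 iterations; failure to bracket or converge is an
  error, never a silent fallback.
* Matching is greedy without replacement in ascending case-id order,
  nearest age first, ties broken by ascending control id — deterministic
  and seed-free. A caliper of 3 years is the default; whether a real study
  used a caliper or frequency matching is usually unstated, so the matcher
  also exposes `allow_partial` rather than guessing.
* Degenerate inputs collapse to defined answers: identical groups give
  F = 0 / p = 1; constant outcomes give slope 0 with $R^2 = 0$; an all-flat
  rate curve integrates to a flat trajectory with stop reason
  `rate_below_epsilon`.
* CSV for tables (inspectable, line-addressable errors), JSON for model
  objects, YAML for configs; the write→read round trip is lossless to
  double precision.

## Problem sizes used by the test suite

The suite validates calibration with 500-replicate null simulations at
n = 200/group, coefficient recovery at n = 2000 cases, distribution
recovery at n = 10 000, and the jackknife grid at the study scale (m = 35,
five visits). These sizes were chosen as the smallest at which the
binomial/Monte-Carlo error of each check is comfortably below its assertion
band.

## Reproducing the study flow

```{r}
library(amytraj)

cfg <- pipeline_config(seed = 1L)
manifest <- run_pipeline(cfg, "amytraj_out")
```

writes every intermediate artifact (visits, matches, annualized changes,
rate-curve JSON, trajectory, association table, sample-size table) plus a
manifest of MD5 hashes; identical seeds give byte-identical artifacts. A
thin command-line wrapper with per-stage subcommands ships in
`inst/cli/amytraj.R`.

## Known limitations

* The generator's clinical scores are unbounded Gaussians; floor/ceiling
  effects of real scales (CDR-SOB ≥ 0, MMSE ≤ 30) are not enforced.
* The vertical-shift model accounts for matching only through the group
  indicator, not block-level random effects.
* Sample sizes use the z approximation and no dropout; both are optimistic
  relative to t-based, attrition-adjusted planning.
* The rate curve is a single Gaussian smooth; multi-smooth or non-Gaussian
  generalized additive modelling is out of scope.
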