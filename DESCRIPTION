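Package: amytraj
Title: Longitudinal Amyloid-PET Trajectory Modelling and Trial Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for modelling the longitudinal accumulation of brain
    beta-amyloid measured by PET standardized uptake value ratios (SUVR) in
    matched case-control cohorts. Provides a synthetic matched-cohort
    generator built on a bounded logistic accumulation law, greedy
    nearest-age matching on sex and APOE e4 status, annualization of
    two-visit changes, penalized B-spline estimation of the rate-of-change
    versus baseline-load curve at a fixed effective degrees of freedom,
    nested spline F tests for group differences and nonlinearity,
    Runge-Kutta integration of the fitted rate curve into a cumulative
    level-versus-time trajectory, simple-regression association tables
    relating amyloid load to clinical decline, blocked analysis of variance
    for matched baseline comparisons, and mixed-model plus jackknife
    per-arm sample-size estimation for slope-reduction clinical trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    lme4,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
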