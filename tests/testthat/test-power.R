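test_that("noise-free common-slope data give exact fixed effects and zero variances", {
  d <- lmm_sample(12, c(0, 1, 2), beta0 = 1, beta1 = 0.02)
  fit <- fit_lmm(d, "y")
  expect_equal(fit$beta1, 0.02, tolerance = 1e-12)
  expect_equal(fit$beta0, 1, tolerance = 1e-12)
  expect_equal(fit$var_intercept, 0)
  expect_equal(fit$var_slope, 0)
  expect_equal(fit$var_residual, 0)
  expect_true(fit$converged)
})

test_that("variance components are recovered on simulated longitudinal data", {
  set.seed(3)
  d <- lmm_sample(500, c(0, 1, 2), beta0 = 5, beta1 = 1,
                  var_int = 1.0, var_slope = 0.25, var_resid = 0.09)
  fit <- fit_lmm(d, "y")
  expect_equal(fit$var_intercept, 1.0, tolerance = 0.10)
  expect_equal(fit$var_slope, 0.25, tolerance = 0.10)
  expect_equal(fit$var_residual, 0.09, tolerance = 0.10)
  expect_equal(fit$beta1, 1, tolerance = 0.05)
})

test_that("fixed effects equal the GLS closed form at the estimated covariance", {
  set.seed(52)
  d <- lmm_sample(60, c(0, 1, 2, 3), beta0 = 2, beta1 = 0.5,
                  var_int = 0.8, var_slope = 0.1, var_resid = 0.2)
  fit <- fit_lmm(d, "y")
  # independent GLS oracle on the balanced design
  tt <- c(0, 1, 2, 3)
  X <- cbind(1, tt)
  Z <- X
  Psi <- matrix(c(fit$var_intercept, fit$cov_int_slope,
                  fit$cov_int_slope, fit$var_slope), 2)
  V <- Z %*% Psi %*% t(Z) + fit$var_residual * diag(4)
  Vi <- solve(V)
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  for (s in unique(d$subject)) {
    ys <- d$y[d$subject == s]
    XtVX <- XtVX + t(X) %*% Vi %*% X
    XtVy <- XtVy + t(X) %*% Vi %*% ys
  }
  beta_gls <- unname(drop(solve(XtVX, XtVy)))
  expect_equal(c(fit$beta0, fit$beta1), beta_gls, tolerance = 1e-8)
})

test_that("the closed-form sample size matches the hand computation", {
  fit <- structure(list(beta1 = 0.02, var_slope = 0.04, var_residual = 0,
                        converged = TRUE), class = "lmm_fit")
  des <- trial_design(alpha = 0.05, power = 0.80, reduction = 0.5,
                      visit_times = c(0, 1, 2))
  n <- required_n(fit, des)
  expect_equal(n, 2 * (qnorm(0.95) + qnorm(0.80))^2 * 0.04 / (0.5 * 0.02)^2,
               tolerance = 1e-12)
  expect_equal(n, 4946.2, tolerance = 0.1)
  expect_equal(ceiling(n), 4947)
})

test_that("halving the detectable reduction exactly quadruples n", {
  fit <- structure(list(beta1 = 0.05, var_slope = 0.01, var_residual = 0.02,
                        converged = TRUE), class = "lmm_fit")
  d50 <- trial_design(reduction = 0.5, visit_times = c(0, 1, 1.5, 2))
  d25 <- trial_design(reduction = 0.25, visit_times = c(0, 1, 1.5, 2))
  expect_equal(required_n(fit, d25) / required_n(fit, d50), 4, tolerance = 1e-12)
})

test_that("with zero residual variance n is invariant to the visit schedule", {
  fit <- structure(list(beta1 = 0.05, var_slope = 0.01, var_residual = 0,
                        converged = TRUE), class = "lmm_fit")
  n1 <- required_n(fit, trial_design(visit_times = c(0, 1)))
  n2 <- required_n(fit, trial_design(visit_times = c(0, 1, 1.5, 2, 3)))
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("required_n is monotone in both variance components", {
  base <- list(beta1 = 0.05, var_slope = 0.01, var_residual = 0.02,
               converged = TRUE)
  des <- trial_design(visit_times = c(0, 1, 2))
  n0 <- required_n(structure(base, class = "lmm_fit"), des)
  up_slope <- base; up_slope$var_slope <- 0.02
  up_res <- base; up_res$var_residual <- 0.04
  expect_gt(required_n(structure(up_slope, class = "lmm_fit"), des), n0)
  expect_gt(required_n(structure(up_res, class = "lmm_fit"), des), n0)
})

test_that("degenerate designs and fits are refused", {
  fit <- structure(list(beta1 = 0, var_slope = 0.01, var_residual = 0.02,
                        converged = TRUE), class = "lmm_fit")
  des <- trial_design(visit_times = c(0, 1, 2))
  expect_error(required_n(fit, des), "slope is zero")
  bad <- structure(list(beta1 = 0.05, var_slope = 0.01, var_residual = 0.02,
                        converged = FALSE), class = "lmm_fit")
  expect_error(required_n(bad, des), "converge")
  expect_error(trial_design(alpha = 0.6), "alpha")
  expect_error(trial_design(reduction = 0), "reduction")
  expect_error(trial_design(visit_times = c(1, 2)), "visit_times")
})

test_that("the jackknife equals brute-force leave-one-out enumeration at m = 6", {
  set.seed(54)
  d <- lmm_sample(6, c(0, 1, 2), beta0 = 3, beta1 = 1,
                  var_int = 0.5, var_slope = 0.2, var_resid = 0.1)
  des <- trial_design(reduction = 0.25, visit_times = c(0, 1, 2))
  jk <- jackknife_sample_size(d, "y", des)
  subjects <- unique(d$subject)
  n_i <- sapply(subjects, function(s) {
    required_n(fit_lmm(d[d$subject != s, ], "y"), des)
  })
  expect_equal(jk$n_per_arm_mean, mean(n_i), tolerance = 1e-10)
  se <- sqrt(5 / 6 * sum((n_i - mean(n_i))^2))
  expect_equal(jk$ci_high - jk$n_per_arm_mean, 1.96 * se, tolerance = 1e-8)
  # CI symmetric about the mean by construction
  expect_equal(jk$n_per_arm_mean - jk$ci_low, jk$ci_high - jk$n_per_arm_mean)
  expect_equal(jk$n_jackknife_replicates, 6)
})

test_that("the jackknife mean approaches the full-sample closed form", {
  set.seed(55)
  d <- lmm_sample(200, c(0, 1, 2), beta0 = 0, beta1 = 0.5,
                  var_int = 0.5, var_slope = 0.1, var_resid = 0.1)
  des <- trial_design(reduction = 0.25, visit_times = c(0, 1, 2))
  full <- required_n(fit_lmm(d, "y"), des)
  jk <- jackknife_sample_size(d, "y", des)
  expect_lt(abs(jk$n_per_arm_mean - full) / full, 0.02)
})

test_that("the sample-size grid has the tabulated structure", {
  cfg <- generator_config(seed = 21)
  trial <- generate_trial_visits(cfg, 35, visit_times = c(0, 1, 1.5, 2, 3))
  tab <- sample_size_table(trial)
  expect_equal(nrow(tab), 32)
  expect_true(all(tab$n_per_arm_mean > 0))
  expect_true(all(tab$ci_low <= tab$n_per_arm_mean &
                    tab$n_per_arm_mean <= tab$ci_high))
  for (outc in unique(tab$outcome)) {
    for (mo in unique(tab$follow_up_months)) {
      cell <- tab[tab$outcome == outc & tab$follow_up_months == mo, ]
      ratio <- cell$n_per_arm_mean[cell$reduction_pct == 25] /
        cell$n_per_arm_mean[cell$reduction_pct == 50]
      expect_gte(ratio, 3.9); expect_lte(ratio, 4.1)
    }
    # longer follow-up never needs more participants
    n25 <- tab$n_per_arm_mean[tab$outcome == outc & tab$reduction_pct == 25]
    mos <- tab$follow_up_months[tab$outcome == outc & tab$reduction_pct == 25]
    expect_true(all(diff(n25[order(mos)]) <= 0))
  }
})

test_that("noisier, flatter outcomes demand larger trials (tabulated ordering)", {
  cfg <- generator_config(seed = 22)
  trial <- generate_trial_visits(cfg, 200, visit_times = c(0, 1, 1.5, 2))
  des <- trial_design(reduction = 0.25, visit_times = c(0, 1, 1.5, 2))
  n_for <- function(outc) required_n(fit_lmm(trial, outc), des)
  ns <- sapply(c("suvr", "cdr_sob", "drs", "mmse"), n_for)
  expect_true(ns["suvr"] < ns["cdr_sob"])
  expect_true(ns["cdr_sob"] < ns["drs"])
  expect_true(ns["drs"] < ns["mmse"])
})
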