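#' Fit a random-intercept, random-slope linear mixed model
#'
#' Fits `y = (b0 + u0i) + (b1 + u1i) t + e` by restricted maximum
#' likelihood, with an unstructured 2x2 covariance for the subject-level
#' random intercept and slope. This is the longitudinal decline model
#' whose variance components drive the trial sample-size formula.
#'
#' A data set that lies exactly on one common line (zero residual, zero
#' random effects) is degenerate for REML; it is detected and returned
#' directly with all variance components zero.
#'
#' @param data long-format data frame with columns `subject`,
#'   `time_years`, and the outcome.
#' @param outcome name of the outcome column.
#' @return An object of class `lmm_fit`: `beta0`, `beta1` (fixed
#'   intercept/slope), `var_intercept`, `var_slope`, `cov_int_slope`,
#'   `var_residual`, `n_subjects`, `converged`, `logLik`.
#' @export
fit_lmm <- function(data, outcome) {
  stopifnot(all(c("subject", "time_years", outcome) %in% names(data)))
  dd <- data.frame(subject = data$subject, time_years = data$time_years,
                   y = data[[outcome]])
  dd <- dd[stats::complete.cases(dd), , drop = FALSE]
  per <- table(dd$subject)
  if (all(per < 2)) stop("no subject has at least 2 visits")
  n_subjects <- length(per)
  if (n_subjects < 3L) stop("need at least 3 subjects")

  # degenerate exact-line data: REML is undefined at zero residual variance
  flat <- stats::lm(y ~ time_years, data = dd)
  if (sum(resid(flat)^2) < 1e-10 * max(1, sum(dd$y^2))) {
    return(structure(list(
      beta0 = unname(coef(flat)[1]), beta1 = unname(coef(flat)[2]),
      var_intercept = 0, var_slope = 0, cov_int_slope = 0, var_residual = 0,
      n_subjects = n_subjects, converged = TRUE, logLik = NA_real_
    ), class = "lmm_fit"))
  }

  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ time_years + (time_years | subject), data = dd,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  ))
  vc <- lme4::VarCorr(fit)$subject
  conv <- length(fit@optinfo$conv$lme4) == 0L
  fe <- lme4::fixef(fit)
  structure(list(
    beta0 = unname(fe["(Intercept)"]), beta1 = unname(fe["time_years"]),
    var_intercept = vc[1, 1], var_slope = vc[2, 2], cov_int_slope = vc[1, 2],
    var_residual = stats::sigma(fit)^2,
    n_subjects = n_subjects, converged = conv,
    logLik = as.numeric(stats::logLik(fit))
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept / random-slope mixed model (REML)\n")
  cat(sprintf("  fixed: intercept %.4g, slope %.4g per year (n = %d subjects)\n",
              x$beta0, x$beta1, x$n_subjects))
  cat(sprintf("  var: intercept %.4g, slope %.4g, cov %.4g, residual %.4g\n",
              x$var_intercept, x$var_slope, x$cov_int_slope, x$var_residual))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Specify a slope-reduction trial design
#'
#' @param alpha one-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @param reduction fraction of the mean annual slope the treatment is
#'   assumed to remove (e.g. 0.25 or 0.50).
#' @param visit_times assessment schedule in years, starting at 0, at
#'   least two visits.
#' @return A validated list of class `trial_design`.
#' @export
trial_design <- function(alpha = 0.05, power = 0.80, reduction = 0.25,
                         visit_times = c(0, 1, 1.5, 2)) {
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  if (power <= 0.5 || power >= 1) stop("power must be in (0.5, 1)")
  if (reduction <= 0 || reduction > 1) stop("reduction must be in (0, 1]")
  if (length(visit_times) < 2L || visit_times[1] != 0 ||
      is.unsorted(visit_times, strictly = TRUE)) {
    stop("visit_times must be >= 2 strictly increasing times starting at 0")
  }
  structure(list(alpha = alpha, power = power, reduction = reduction,
                 visit_times = visit_times), class = "trial_design")
}

#' Per-arm sample size to detect a fractional slope reduction
#'
#' Closed-form normal-approximation sample size for a two-arm comparison
#' of mean slopes under the random-slope mixed model. With visit times
#' `t_j`, `Sxx = sum_j (t_j - mean(t))^2`, the variance of one subject's
#' estimated slope is `V = var_slope + var_residual / Sxx`, and
#' `n per arm = 2 (z_{1-alpha} + z_{power})^2 V / (reduction * beta1)^2`.
#' The value is returned unrounded; tabulated integers are its ceiling.
#'
#' @param fit an [fit_lmm()] result (must have converged).
#' @param design a [trial_design()].
#' @param force fit a non-converged model anyway.
#' @return Unrounded per-arm sample size (scalar).
#' @export
required_n <- function(fit, design, force = FALSE) {
  stopifnot(inherits(fit, "lmm_fit"), inherits(design, "trial_design"))
  if (!fit$converged && !force) {
    stop("mixed-model fit did not converge; pass force = TRUE to override")
  }
  if (fit$beta1 == 0) stop("fixed slope is zero: no detectable effect")
  tt <- design$visit_times
  sxx <- sum((tt - mean(tt))^2)
  if (sxx == 0) stop("visit schedule has zero spread")
  v <- fit$var_slope + fit$var_residual / sxx
  zq <- stats::qnorm(1 - design$alpha) + stats::qnorm(design$power)
  2 * zq^2 * v / (design$reduction * fit$beta1)^2
}

#' Jackknife sample-size estimate with asymptotic confidence interval
#'
#' Leave-one-subject-out resampling of the mixed-model sample-size
#' calculation: for each subject the model is refitted without them and
#' [required_n()] recomputed; the estimate is the mean of the leave-one-
#' out values with jackknife standard error
#' `sqrt((m-1)/m * sum((n_i - mean)^2))` and a normal 95% interval.
#' Replicates whose refit does not converge are dropped and counted; more
#' than 20% dropped is an error.
#'
#' @param data long-format data as for [fit_lmm()].
#' @param outcome outcome column name.
#' @param design a [trial_design()].
#' @return A data frame of class `amy_samplesize` with `outcome`,
#'   `follow_up_months`, `reduction_pct`, `n_per_arm_mean`, `ci_low`,
#'   `ci_high`, `n_jackknife_replicates`.
#' @export
jackknife_sample_size <- function(data, outcome, design) {
  m <- length(unique(data$subject))
  if (m < 6L) stop("need at least 6 subjects for the jackknife")
  fits <- jackknife_fits(data, outcome)
  dropped <- sum(vapply(fits, is.null, logical(1)))
  if (dropped > 0.2 * m) {
    stop(sprintf("%d of %d jackknife replicates failed to converge", dropped, m))
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  n_i <- vapply(fits, required_n, numeric(1), design = design)
  summarize_jackknife(n_i, outcome, design)
}

# Follow-up duration (months) -> cumulative assessment schedule (years).
# Readings accrue at 12, 18, 24 and 36 months, so a longer trial keeps all
# earlier assessments.
schedule_for_months <- function(months) {
  readings <- c(12, 18, 24, 36)
  if (!months %in% readings) {
    stop("follow-up must be one of ", paste(readings, collapse = ", "),
         " months")
  }
  c(0, readings[readings <= months]) / 12
}

# Leave-one-subject-out LMM refits for one outcome; non-converged refits
# are returned as NULL and counted by the caller.
jackknife_fits <- function(data, outcome) {
  subjects <- unique(data$subject)
  lapply(subjects, function(s) {
    f <- tryCatch(fit_lmm(data[data$subject != s, , drop = FALSE], outcome),
                  error = function(e) NULL)
    if (!is.null(f) && !f$converged) f <- NULL
    f
  })
}

summarize_jackknife <- function(n_i, outcome, design) {
  mm <- length(n_i)
  n_bar <- mean(n_i)
  se <- sqrt((mm - 1) / mm * sum((n_i - n_bar)^2))
  out <- data.frame(
    outcome = outcome,
    follow_up_months = round(max(design$visit_times) * 12),
    reduction_pct = design$reduction * 100,
    n_per_arm_mean = n_bar,
    ci_low = n_bar - 1.96 * se,
    ci_high = n_bar + 1.96 * se,
    n_jackknife_replicates = mm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("amy_samplesize", "data.frame")
  out
}

#' Full sample-size table over outcomes, durations and slope reductions
#'
#' For each outcome, one random-slope mixed model is fitted to the full
#' assessment series (with leave-one-subject-out jackknife refits); every
#' follow-up duration and slope reduction is then evaluated with
#' [required_n()] on those same fits. A duration resolves to the
#' cumulative schedule of readings at 12, 18, 24 and 36 months (a
#' 24-month trial assesses at 0, 12, 18 and 24 months), and enters the
#' closed form only through the schedule's time spread; slope and
#' variance components come from the single per-outcome model. A
#' 12-month, two-visit schedule therefore needs no (unidentifiable)
#' two-visit refit.
#'
#' @param trial_data long-format case-arm data as produced by
#'   [generate_trial_visits()] with the full assessment series.
#' @param outcomes outcome columns (default SUVR and the global clinical
#'   scales).
#' @param follow_ups durations in months.
#' @param reductions slope reductions as percentages.
#' @param alpha,power test size (one-sided) and power.
#' @return A data frame with one row per outcome x duration x reduction.
#' @export
sample_size_table <- function(trial_data,
                              outcomes = c("suvr", "cdr_sob", "drs", "mmse"),
                              follow_ups = c(12, 18, 24, 36),
                              reductions = c(25, 50),
                              alpha = 0.05, power = 0.80) {
  m <- length(unique(trial_data$subject))
  rows <- list()
  for (outc in outcomes) {
    fits <- jackknife_fits(trial_data, outc)
    dropped <- sum(vapply(fits, is.null, logical(1)))
    if (dropped > 0.2 * m) {
      stop(sprintf("outcome %s: %d of %d jackknife replicates failed to converge",
                   outc, dropped, m))
    }
    fits <- fits[!vapply(fits, is.null, logical(1))]
    for (months in follow_ups) {
      sched <- schedule_for_months(months)
      for (red in reductions) {
        design <- trial_design(alpha, power, red / 100, sched)
        n_i <- vapply(fits, required_n, numeric(1), design = design)
        rows[[paste(outc, months, red)]] <-
          summarize_jackknife(n_i, outc, design)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
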