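# Truncated-normal draws by inverse-CDF, so sequences are reproducible and
# monotone in the underlying uniform stream.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Mean and SD of a normal(mu, sigma) truncated to (lower, upper).
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) return(c(mean = NA_real_, sd = NA_real_))
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying normal parameters whose truncation to (lower, upper) best
# reproduces a requested mean/SD (exactly, when feasible). Plain truncation
# of the requested parameters would bias the realized moments whenever the
# truncation bites, so the configured values would not be recovered in
# large samples.
truncnorm_match <- function(mean, sd, lower, upper) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    if (any(is.na(mo))) return(1e6)
    ((mo["mean"] - mean) / max(sd, 1e-6))^2 + ((mo["sd"] - sd) / max(sd, 1e-6))^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Exact composition: when n * fraction is integral, assign exactly that many
# positives in a random order; otherwise fall back to independent draws.
assign_composition <- function(n, fraction) {
  if (n == 0) return(logical(0))
  target <- n * fraction
  if (abs(target - round(target)) < 1e-9) {
    k <- as.integer(round(target))
    sample(c(rep(TRUE, k), rep(FALSE, n - k)))
  } else {
    stats::runif(n) < fraction
  }
}

make_participants <- function(n, group, prefix, cfg, anchor = NULL) {
  if (n == 0) {
    return(data.frame(
      id = character(0), group = character(0), age = numeric(0),
      sex = character(0), apoe4 = character(0),
      latent_baseline_level = numeric(0), match_block = character(0),
      stringsAsFactors = FALSE
    ))
  }
  dist <- cfg$baseline_level_distribution[[group]]
  par <- truncnorm_match(dist[["mean"]], dist[["sd"]],
                         cfg$floor_L, cfg$ceiling_U)
  out <- data.frame(
    id = sprintf("%s_%04d", prefix, seq_len(n)),
    group = group,
    age = stats::rnorm(n, cfg$age_mean, cfg$age_sd),
    sex = ifelse(assign_composition(n, cfg$male_fraction), "M", "F"),
    apoe4 = ifelse(assign_composition(n, cfg$apoe4_fraction),
                   "carrier", "noncarrier"),
    latent_baseline_level = rtruncnorm(
      n, par[["mu"]], par[["sigma"]],
      lower = cfg$floor_L + 1e-9, upper = cfg$ceiling_U - 1e-9
    ),
    match_block = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(anchor) && nrow(anchor)) {
    out$age <- anchored_pool_ages(out, anchor, cfg)
  }
  out
}

# Control candidates emulate a registry's pre-screened list: each candidate
# enters the pool because they are age-compatible with some index case of
# their own sex-by-APOE stratum (age = anchor case's age plus a uniform
# screening slop). Strata with no case fall back to population ages.
anchored_pool_ages <- function(pool, cases, cfg) {
  ages <- pool$age
  jit <- cfg$pool_age_jitter
  for (sx in unique(pool$sex)) {
    for (ap in unique(pool$apoe4)) {
      idx <- which(pool$sex == sx & pool$apoe4 == ap)
      anchors <- cases$age[cases$sex == sx & cases$apoe4 == ap]
      if (!length(idx) || !length(anchors)) next
      picked <- anchors[sample.int(length(anchors), length(idx), replace = TRUE)]
      ages[idx] <- picked + stats::runif(length(idx), -jit, jit)
    }
  }
  ages
}

# Annual clinical change for one participant: slope coupled to baseline
# amyloid load and to the latent per-year SUVR change.
clinical_slopes <- function(baseline_suvr, dsuvr_per_year, couplings) {
  n <- length(baseline_suvr)
  out <- matrix(NA_real_, n, length(MEASURES), dimnames = list(NULL, MEASURES))
  for (m in MEASURES) {
    row <- couplings[couplings$measure == m, ]
    out[, m] <- row$intercept + row$c_base * baseline_suvr +
      row$c_rate * dsuvr_per_year + stats::rnorm(n, 0, row$resid_sd)
  }
  out
}

#' Generate a synthetic matched-cohort longitudinal data set
#'
#' Simulates index cases and a control pool with the statistical structure
#' the downstream analyses assume. Each participant receives a baseline
#' visit at time 0 and one follow-up visit after a group-specific
#' truncated-normal interval. The latent amyloid level follows the bounded
#' logistic accumulation law [logistic_level()]; observed SUVR adds
#' independent Gaussian measurement noise at each visit. Each clinical
#' score at follow-up equals its baseline value plus
#' `t * (intercept + c_base * baseline SUVR + c_rate * dSUVR/yr + residual)`
#' using the configured couplings, so known effect sizes are recoverable
#' by regression.
#'
#' Deterministic given `config$seed`: two calls with the same configuration
#' produce identical tables.
#'
#' @param config an [generator_config()] object.
#' @return An object of class `amy_cohort`: a list with `participants`
#'   (one row per person, including the latent baseline level) and
#'   `visits` (long format, one row per visit, columns as written by
#'   [write_visits()]).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  withr::with_seed(stage_seed(config$seed, "generate_cohort"), {
    cases <- make_participants(config$n_cases, "case", "case", config)
    ctrls <- make_participants(config$control_pool_size, "control", "ctrl",
                               config, anchor = cases)
    participants <- rbind(cases, ctrls)
    visits <- cohort_visits(participants, config)
  })
  structure(list(participants = participants, visits = visits),
            class = "amy_cohort")
}

cohort_visits <- function(participants, cfg) {
  n <- nrow(participants)
  empty <- data.frame(matrix(nrow = 0, ncol = length(VISIT_COLUMNS)))
  names(empty) <- VISIT_COLUMNS
  if (n == 0) return(empty)

  iv <- cfg$interval
  interval <- numeric(n)
  for (g in c("case", "control")) {
    idx <- participants$group == g
    interval[idx] <- rtruncnorm(sum(idx), iv[[g]]["mean"], iv[[g]]["sd"],
                                lower = cfg$interval_min)
  }
  A0 <- participants$latent_baseline_level
  A1 <- logistic_level(A0, cfg$growth_r, cfg$floor_L, cfg$ceiling_U, interval)
  latent_rate <- (A1 - A0) / interval

  suvr_base <- A0 + stats::rnorm(n, 0, cfg$suvr_noise_sd)
  suvr_fu <- A1 + stats::rnorm(n, 0, cfg$suvr_noise_sd)

  base_scores <- matrix(NA_real_, n, length(MEASURES),
                        dimnames = list(NULL, MEASURES))
  for (m in MEASURES) {
    row <- cfg$clinical_baselines[cfg$clinical_baselines$measure == m, ]
    for (g in c("case", "control")) {
      idx <- participants$group == g
      base_scores[idx, m] <- stats::rnorm(sum(idx), row[[paste0(g, "_mean")]],
                                          row[[paste0(g, "_sd")]])
    }
  }
  slopes <- clinical_slopes(A0, latent_rate, cfg$clinical_couplings)
  fu_scores <- base_scores + slopes * interval

  if (cfg$missing_prob > 0) {
    for (scores in c("base_scores", "fu_scores")) {
      m <- get(scores)
      m[stats::runif(length(m)) < cfg$missing_prob] <- NA_real_
      assign(scores, m)
    }
  }

  two <- function(x) rep(x, each = 2L)
  visits <- data.frame(
    participant_id = two(participants$id),
    group = two(participants$group),
    age = two(participants$age),
    sex = two(participants$sex),
    apoe4 = two(participants$apoe4),
    time_years = as.vector(rbind(0, interval)),
    suvr = as.vector(rbind(suvr_base, suvr_fu)),
    stringsAsFactors = FALSE
  )
  for (m in MEASURES) {
    visits[[m]] <- as.vector(rbind(base_scores[, m], fu_scores[, m]))
  }
  visits[, VISIT_COLUMNS]
}

#' Simulate a multi-visit trial schedule from the latent cohort model
#'
#' Draws a fresh sample of case-like (probable-DLB arm) subjects and
#' observes each of them at a fixed schedule of visit times, using the
#' same latent accumulation and clinical-slope model as
#' [generate_cohort()] plus per-visit measurement noise. This is the input
#' the trial sample-size machinery fits its mixed models to.
#'
#' @param config an [generator_config()] object.
#' @param n_subjects number of subjects to simulate.
#' @param visit_times visit schedule in years, starting at 0.
#' @param seed integer seed; defaults to a substream of `config$seed`.
#' @return A long-format data frame with columns `subject`, `time_years`,
#'   `suvr`, and one column per clinical measure.
#' @export
generate_trial_visits <- function(config, n_subjects,
                                  visit_times = c(0, 1, 1.5, 2),
                                  seed = NULL) {
  validate_config(config)
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (visit_times[1] != 0 || is.unsorted(visit_times, strictly = TRUE)) {
    stop("visit_times must strictly increase from 0")
  }
  if (is.null(seed)) seed <- stage_seed(config$seed, "trial_visits")
  withr::with_seed(seed, {
    dist <- config$baseline_level_distribution$case
    par <- truncnorm_match(dist[["mean"]], dist[["sd"]],
                           config$floor_L, config$ceiling_U)
    A0 <- rtruncnorm(n_subjects, par[["mu"]], par[["sigma"]],
                     lower = config$floor_L + 1e-9,
                     upper = config$ceiling_U - 1e-9)
    nv <- length(visit_times)
    tt <- rep(visit_times, times = n_subjects)
    A0v <- rep(A0, each = nv)
    latent <- logistic_level(A0v, config$growth_r, config$floor_L,
                             config$ceiling_U, tt)
    out <- data.frame(
      subject = rep(sprintf("trial_%04d", seq_len(n_subjects)), each = nv),
      time_years = tt,
      suvr = latent + stats::rnorm(length(tt), 0, config$suvr_noise_sd),
      stringsAsFactors = FALSE
    )
    # clinical slope heterogeneity comes from the baseline-load coupling:
    # reference rate is the subject's latent annualized change over the
    # schedule (or the instantaneous rate for a degenerate schedule).
    horizon <- max(visit_times)
    Ah <- logistic_level(A0, config$growth_r, config$floor_L,
                         config$ceiling_U, horizon)
    ref_rate <- (Ah - A0) / horizon
    slopes <- clinical_slopes(A0, ref_rate, config$clinical_couplings)
    for (m in MEASURES) {
      row <- config$clinical_baselines[config$clinical_baselines$measure == m, ]
      base <- stats::rnorm(n_subjects, row$case_mean, row$case_sd)
      noise_sd <- config$clinical_visit_noise[[m]]
      out[[m]] <- rep(base, each = nv) + rep(slopes[, m], each = nv) * tt +
        stats::rnorm(length(tt), 0, noise_sd)
    }
    out
  })
}

#' @export
print.amy_cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat("Synthetic matched-cohort data set\n")
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  visits: %d rows\n", nrow(x$visits)))
  invisible(x)
}
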