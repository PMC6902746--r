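# Shared fixture builders. Everything is generated in code; no data files.

# A small, fast generator configuration for structural tests.
small_config <- function(seed = 1, ...) {
  generator_config(n_cases = 20, control_pool_size = 120, seed = seed, ...)
}

# Couplings with every stochastic component silenced.
noiseless_couplings <- function() {
  cc <- amytraj:::default_couplings()
  cc$resid_sd <- 0
  cc
}

# Coupling table with one channel isolated: the other channel's
# coefficients are zeroed so that single-predictor regressions identify
# the structural coefficient (baseline load and latent rate are otherwise
# deterministically confounded).
isolated_couplings <- function(channel = c("base", "rate"), resid_sd = NULL) {
  channel <- match.arg(channel)
  cc <- amytraj:::default_couplings()
  if (channel == "base") cc$c_rate <- 0 else cc$c_base <- 0
  if (!is.null(resid_sd)) cc$resid_sd <- resid_sd
  cc
}

# Two-visit rows for one participant, for annualization tests.
visit_pair <- function(id, t1, suvr0, suvr1, group = "case", ...) {
  extras <- list(...)
  row <- function(time, suvr, which) {
    d <- data.frame(participant_id = id, group = group, age = 70, sex = "M",
                    apoe4 = "carrier", time_years = time, suvr = suvr,
                    stringsAsFactors = FALSE)
    for (m in amytraj:::MEASURES) {
      vals <- extras[[m]]
      d[[m]] <- if (is.null(vals)) NA_real_ else vals[which]
    }
    d
  }
  rbind(row(0, suvr0, 1L), row(t1, suvr1, 2L))
}

# Annualized-change-like frame from raw x/y vectors, for the curve fits.
rate_frame <- function(x, y, group = "case") {
  data.frame(participant_id = sprintf("p%04d", seq_along(x)), group = group,
             baseline_suvr = x, dsuvr_per_year = y, interval = 1,
             stringsAsFactors = FALSE)
}

# Draws from the study's inverted-U rate law plus Gaussian noise.
quadratic_rate_sample <- function(n, noise_sd = 0.015, r = 0.112,
                                  L = 1.1, U = 2.5, group = "case") {
  x <- runif(n, L + 0.01, U - 0.05)
  y <- logistic_rate(x, r, L, U) + rnorm(n, 0, noise_sd)
  rate_frame(x, y, group)
}

# Balanced random-intercept/random-slope longitudinal sample.
lmm_sample <- function(n_subjects, visit_times, beta0 = 0, beta1 = 0.02,
                       var_int = 0, var_slope = 0, var_resid = 0) {
  nv <- length(visit_times)
  b0 <- rnorm(n_subjects, 0, sqrt(var_int))
  b1 <- rnorm(n_subjects, 0, sqrt(var_slope))
  tt <- rep(visit_times, times = n_subjects)
  data.frame(
    subject = rep(sprintf("s%04d", seq_len(n_subjects)), each = nv),
    time_years = tt,
    y = rep(beta0 + b0, each = nv) + rep(beta1 + b1, each = nv) * tt +
      rnorm(n_subjects * nv, 0, sqrt(var_resid)),
    stringsAsFactors = FALSE
  )
}
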