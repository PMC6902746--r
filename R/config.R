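#' @importFrom stats rnorm runif qnorm quantile sd var lm pf pt coef anova
#' @importFrom stats predict resid fitted complete.cases aov setNames rbinom
#' @importFrom utils read.csv write.csv modifyList
NULL

# Clinical / cognitive measures carried on every visit record, in the order
# reported by the association table.
MEASURES <- c("drs", "cdr_sob", "mmse", "updrs3", "avlt", "bnt", "tmt_a", "rcf")

VISIT_COLUMNS <- c(
  "participant_id", "group", "age", "sex", "apoe4", "time_years", "suvr",
  "cdr_sob", "mmse", "drs", "updrs3", "avlt", "bnt", "tmt_a", "rcf"
)

# Default slope couplings: annual clinical change for a case is modelled as
#   intercept + c_base * baseline SUVR + c_rate * (dSUVR/year) + N(0, resid_sd).
# c_base / c_rate are the simple-regression effect sizes observed in probable
# DLB; intercepts are calibration constants chosen so that at the typical case
# baseline (SUVR 1.58, rate 0.03/yr) the mean annual declines are clinically
# plausible (DRS about -7/yr, CDR-SOB about +1.8/yr, MMSE about -1.5/yr).
default_couplings <- function() {
  data.frame(
    measure   = c("drs", "cdr_sob", "mmse", "updrs3", "avlt", "bnt", "tmt_a", "rcf"),
    intercept = c(30.25, -1.69, 2.91, 3.27, 3.25, 3.19, -65.22, 4.33),
    c_base    = c(-22.40, 1.90, -2.25, -0.93, -2.09, -2.39, 43.43, -4.26),
    c_rate    = c(-62.09, 16.17, -28.40, 6.66, -25.05, -13.81, 153.42, 30.08),
    resid_sd  = c(13.6, 1.49, 4.20, 4.00, 1.82, 1.72, 28.1, 7.86),
    stringsAsFactors = FALSE
  )
}

# Baseline score distributions per group. Cognitively-unimpaired values for
# DRS, BNT and RCF are not tabulated for the reference cohorts; plausible
# healthy means/SDs are used (near-ceiling performance).
default_clinical_baselines <- function() {
  data.frame(
    measure      = c("drs", "cdr_sob", "mmse", "updrs3", "avlt", "bnt", "tmt_a", "rcf"),
    case_mean    = c(128.6, 3.4, 24.3, 9.1, 3.2, 25.3, 69.0, 17.9),
    case_sd      = c(8.9, 1.8, 4.7, 6.0, 3.4, 4.7, 38.4, 10.5),
    control_mean = c(140.0, 0.0, 28.5, 0.4, 8.2, 27.5, 33.6, 32.0),
    control_sd   = c(3.0, 0.2, 1.1, 1.2, 2.9, 2.0, 9.0, 3.0),
    stringsAsFactors = FALSE
  )
}

# Within-person per-visit measurement noise of each score, used when a
# multi-visit trial schedule is simulated from the same latent model.
default_visit_noise <- function() {
  c(drs = 4.0, cdr_sob = 0.5, mmse = 1.5, updrs3 = 2.0,
    avlt = 1.0, bnt = 1.0, tmt_a = 8.0, rcf = 3.0)
}

#' Configuration for the synthetic matched-cohort generator
#'
#' Builds (and validates) the full parameter set of the cohort simulator.
#' The defaults emulate a mild probable-DLB sample with 4:1 matched
#' cognitively unimpaired (CU) controls: 35 cases of whom 31 are men and
#' 16 APOE e4 carriers, case baseline amyloid load centred at SUVR 1.58
#' (SD 0.41) versus 1.36 (SD 0.22) in controls, interscan intervals of
#' about 1.2 years in cases and 2.4 years in controls, and a bounded
#' logistic accumulation law between floor 1.1 and ceiling 2.5 SUVR with
#' growth coefficient 0.112 per (SUVR x year), so that the accumulation
#' rate peaks at about 0.055 SUVR/year at a level of 1.8.
#'
#' @param n_cases number of index cases.
#' @param control_pool_size size of the unmatched control pool that the
#'   matching stage later draws from.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param floor_L,ceiling_U lower/upper asymptotes of the accumulation law
#'   (SUVR).
#' @param growth_r logistic growth coefficient, 1/(SUVR x year).
#' @param baseline_level_distribution list with `case` and `control`
#'   entries, each `c(mean=, sd=)` of the latent baseline SUVR; draws are
#'   truncated to the open interval `(floor_L, ceiling_U)`.
#' @param age_mean,age_sd case age distribution in years.
#' @param pool_age_jitter half-width (years) of the uniform screening slop
#'   used for control-pool ages: each candidate control's age is drawn as
#'   the age of a random index case of the same sex-by-APOE stratum plus
#'   `Uniform(-jitter, +jitter)`, emulating a registry's pre-screened
#'   candidate list (strata without cases fall back to population ages).
#' @param male_fraction,apoe4_fraction group composition; when
#'   `n * fraction` is an integer the count is assigned exactly rather
#'   than by independent coin flips, so tabulated compositions are
#'   reproduced verbatim.
#' @param interval list with `case` / `control` entries `c(mean=, sd=)`
#'   of the baseline-to-follow-up interval in years (truncated normal,
#'   minimum `interval_min`).
#' @param interval_min shortest admissible follow-up interval (years).
#' @param suvr_noise_sd within-person SUVR measurement noise (SUVR units)
#'   added independently at every visit.
#' @param clinical_couplings data frame with columns `measure`,
#'   `intercept`, `c_base`, `c_rate`, `resid_sd` controlling the annual
#'   clinical change model (see Details of [generate_cohort()]).
#' @param clinical_baselines data frame of per-measure, per-group baseline
#'   score means/SDs.
#' @param clinical_visit_noise named vector of per-visit measurement noise
#'   for each score, used only by multi-visit trial schedules.
#' @param missing_prob probability that any one clinical score is masked
#'   missing-at-random (default 0).
#' @return A validated list of class `amy_config`.
#' @export
generator_config <- function(n_cases = 35,
                             control_pool_size = 1000,
                             seed = 1L,
                             floor_L = 1.1,
                             ceiling_U = 2.5,
                             growth_r = 0.112,
                             baseline_level_distribution = list(
                               case = c(mean = 1.58, sd = 0.41),
                               control = c(mean = 1.36, sd = 0.22)
                             ),
                             age_mean = 69.6,
                             age_sd = 7.3,
                             pool_age_jitter = 4,
                             male_fraction = 31 / 35,
                             apoe4_fraction = 16 / 35,
                             interval = list(
                               case = c(mean = 1.2, sd = 0.4),
                               control = c(mean = 2.4, sd = 1.0)
                             ),
                             interval_min = 0.5,
                             suvr_noise_sd = 0.02,
                             clinical_couplings = default_couplings(),
                             clinical_baselines = default_clinical_baselines(),
                             clinical_visit_noise = default_visit_noise(),
                             missing_prob = 0) {
  cfg <- list(
    n_cases = as.integer(n_cases),
    control_pool_size = as.integer(control_pool_size),
    seed = as.integer(seed),
    floor_L = floor_L, ceiling_U = ceiling_U, growth_r = growth_r,
    baseline_level_distribution = baseline_level_distribution,
    age_mean = age_mean, age_sd = age_sd,
    pool_age_jitter = pool_age_jitter,
    male_fraction = male_fraction, apoe4_fraction = apoe4_fraction,
    interval = interval, interval_min = interval_min,
    suvr_noise_sd = suvr_noise_sd,
    clinical_couplings = clinical_couplings,
    clinical_baselines = clinical_baselines,
    clinical_visit_noise = clinical_visit_noise,
    missing_prob = missing_prob
  )
  class(cfg) <- "amy_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  required <- c(
    "n_cases", "control_pool_size", "seed", "floor_L", "ceiling_U",
    "growth_r", "baseline_level_distribution", "age_mean", "age_sd",
    "pool_age_jitter", "male_fraction", "apoe4_fraction", "interval",
    "interval_min",
    "suvr_noise_sd", "clinical_couplings", "clinical_baselines",
    "clinical_visit_noise", "missing_prob"
  )
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing required field(s): ", paste(missing, collapse = ", "))
  }
  if (cfg$n_cases < 0) stop("n_cases must be nonnegative")
  if (cfg$control_pool_size < 0) stop("control_pool_size must be nonnegative")
  if (cfg$floor_L >= cfg$ceiling_U) stop("floor_L must be below ceiling_U")
  if (cfg$growth_r <= 0) stop("growth_r must be positive")
  sds <- c(cfg$age_sd, cfg$suvr_noise_sd,
           cfg$baseline_level_distribution$case["sd"],
           cfg$baseline_level_distribution$control["sd"],
           cfg$interval$case["sd"], cfg$interval$control["sd"],
           cfg$clinical_couplings$resid_sd)
  if (any(sds < 0)) stop("all standard deviations must be nonnegative")
  fr <- c(cfg$male_fraction, cfg$apoe4_fraction, cfg$missing_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!all(MEASURES %in% cfg$clinical_couplings$measure)) {
    stop("clinical_couplings must cover every measure")
  }
  if (!all(MEASURES %in% cfg$clinical_baselines$measure)) {
    stop("clinical_baselines must cover every measure")
  }
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Every entry of the file overrides the corresponding
#' [generator_config()] default; absent entries keep their defaults.
#' Tabular fields (`clinical_couplings`, `clinical_baselines`) are given
#' as lists of named rows.
#'
#' @param path path to a YAML configuration file.
#' @return An `amy_config` object.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  stopifnot(is.list(raw))
  args <- raw
  for (fld in c("clinical_couplings", "clinical_baselines")) {
    if (!is.null(args[[fld]]) && !is.data.frame(args[[fld]])) {
      args[[fld]] <- do.call(rbind, lapply(args[[fld]], function(row) {
        as.data.frame(row, stringsAsFactors = FALSE)
      }))
    }
  }
  for (fld in c("baseline_level_distribution", "interval")) {
    if (!is.null(args[[fld]])) {
      args[[fld]] <- lapply(args[[fld]], unlist)
    }
  }
  if (!is.null(args$clinical_visit_noise)) {
    args$clinical_visit_noise <- unlist(args$clinical_visit_noise)
  }
  do.call(generator_config, args)
}

#' Write a generator configuration to YAML
#'
#' @param config an `amy_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  for (fld in c("clinical_couplings", "clinical_baselines")) {
    df <- out[[fld]]
    out[[fld]] <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  out$clinical_visit_noise <- as.list(out$clinical_visit_noise)
  for (fld in c("baseline_level_distribution", "interval")) {
    out[[fld]] <- lapply(out[[fld]], as.list)
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.amy_config <- function(x, ...) {
  cat("Synthetic matched-cohort generator configuration\n")
  cat(sprintf("  cases: %d, control pool: %d, seed: %d\n",
              x$n_cases, x$control_pool_size, x$seed))
  cat(sprintf("  accumulation law: logistic on (%.2f, %.2f), r = %.3f /(SUVR*yr)\n",
              x$floor_L, x$ceiling_U, x$growth_r))
  cat(sprintf("  baseline SUVR: cases %.2f (%.2f), controls %.2f (%.2f)\n",
              x$baseline_level_distribution$case["mean"],
              x$baseline_level_distribution$case["sd"],
              x$baseline_level_distribution$control["mean"],
              x$baseline_level_distribution$control["sd"]))
  cat(sprintf("  SUVR measurement noise: %.3f, missingness: %.2f\n",
              x$suvr_noise_sd, x$missing_prob))
  invisible(x)
}

# Deterministic per-stage seed derived from the master seed, so pipeline
# stages can be rerun in isolation without sharing RNG state.
stage_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483563L
  as.integer((h + as.numeric(seed) * 7919) %% 2147483563L)
}
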