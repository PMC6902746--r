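test_that("the generator is deterministic given its seed", {
  a <- generate_cohort(small_config(seed = 42))
  b <- generate_cohort(small_config(seed = 42))
  expect_identical(a, b)
  c <- generate_cohort(small_config(seed = 43))
  expect_false(identical(a$visits, c$visits))
})

test_that("generation is insensitive to ambient RNG state", {
  set.seed(1); a <- generate_cohort(small_config(seed = 5))
  set.seed(999); b <- generate_cohort(small_config(seed = 5))
  expect_identical(a, b)
})

test_that("integral compositions are assigned exactly, not by coin flips", {
  coh <- generate_cohort(generator_config(seed = 3))
  cases <- coh$participants[coh$participants$group == "case", ]
  expect_equal(nrow(cases), 35)
  expect_equal(sum(cases$sex == "M"), 31)
  expect_equal(sum(cases$apoe4 == "carrier"), 16)
})

test_that("an empty cohort request yields empty tables", {
  coh <- generate_cohort(generator_config(n_cases = 0, control_pool_size = 0))
  expect_equal(nrow(coh$participants), 0)
  expect_equal(nrow(coh$visits), 0)
  expect_error(generator_config(n_cases = -1), "nonnegative")
})

test_that("with all noise silenced, follow-up SUVR equals the closed form", {
  cfg <- generator_config(
    n_cases = 30, control_pool_size = 30, seed = 9,
    suvr_noise_sd = 0, clinical_couplings = noiseless_couplings()
  )
  coh <- generate_cohort(cfg)
  for (pid in coh$participants$id) {
    vv <- coh$visits[coh$visits$participant_id == pid, ]
    base <- vv[vv$time_years == 0, ]
    fu <- vv[vv$time_years > 0, ]
    a0 <- coh$participants$latent_baseline_level[coh$participants$id == pid]
    expect_equal(base$suvr, a0)
    expect_equal(fu$suvr,
                 logistic_level(a0, cfg$growth_r, cfg$floor_L, cfg$ceiling_U,
                                fu$time_years))
    expect_gte(fu$suvr, base$suvr)
  }
})

test_that("visit records satisfy their structural invariants", {
  coh <- generate_cohort(small_config(seed = 2))
  vv <- coh$visits
  expect_true(all(vv$time_years >= 0))
  expect_true(all(vv$suvr > 0))
  n_baseline <- tapply(vv$time_years == 0, vv$participant_id, sum)
  expect_true(all(n_baseline == 1))
  expect_true(all(table(vv$participant_id) == 2))
  expect_false(any(duplicated(coh$participants$id)))
  expect_true(all(vv$participant_id %in% coh$participants$id))
})

test_that("configured baseline moments are recovered in large samples", {
  cfg <- generator_config(n_cases = 0, control_pool_size = 10000, seed = 4)
  coh <- generate_cohort(cfg)
  lv <- coh$participants$latent_baseline_level
  want <- cfg$baseline_level_distribution$control
  expect_equal(mean(lv), unname(want["mean"]), tolerance = 0.02)
  expect_equal(sd(lv), unname(want["sd"]), tolerance = 0.02)
})

test_that("empirical per-year change peaks mid-range as an inverted U", {
  cfg <- generator_config(n_cases = 2500, control_pool_size = 2500, seed = 8)
  ann <- annualize(generate_cohort(cfg)$visits)
  bins <- cut(ann$baseline_suvr, breaks = seq(1.1, 2.5, by = 0.1))
  running_mean <- tapply(ann$dsuvr_per_year, bins, mean)
  centers <- seq(1.15, 2.45, by = 0.1)
  peak <- centers[which.max(running_mean)]
  expect_gte(peak, 1.7)
  expect_lte(peak, 1.9)
})

test_that("missingness masks scores at the configured rate", {
  cfg <- generator_config(n_cases = 400, control_pool_size = 0, seed = 5,
                          missing_prob = 0.2)
  vv <- generate_cohort(cfg)$visits
  frac <- mean(is.na(as.matrix(vv[, amytraj:::MEASURES])))
  expect_equal(frac, 0.2, tolerance = 0.05)
  cfg0 <- generator_config(n_cases = 50, control_pool_size = 0, seed = 5)
  expect_false(any(is.na(generate_cohort(cfg0)$visits$mmse)))
})

test_that("config validation names the missing field", {
  cfg <- generator_config()
  cfg$growth_r <- NULL
  expect_error(amytraj:::validate_config(cfg), "growth_r")
  expect_error(generator_config(floor_L = 2.5, ceiling_U = 1.1), "floor_L")
  expect_error(generator_config(male_fraction = 1.2), "fractions")
})

test_that("configs round-trip through YAML", {
  cfg <- generator_config(seed = 77, suvr_noise_sd = 0.035)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
})
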