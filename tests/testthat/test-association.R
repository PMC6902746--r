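test_that("a constant outcome gives coefficient 0 and r-squared 0", {
  d <- data.frame(baseline_suvr = c(1.2, 1.4, 1.6, 1.8),
                  ddrs_per_year = 0)
  res <- fit_association(d, "drs", "baseline_suvr")
  expect_equal(res$coefficient, 0)
  expect_equal(res$r_squared, 0)
  expect_equal(res$n_used, 4)
})

test_that("coefficients match the closed-form OLS normal equations", {
  x <- c(1.1, 1.3, 1.5, 1.8, 2.0, 2.4)
  y <- c(0.5, -1.2, 0.3, -2.0, -1.1, -3.4)
  d <- data.frame(baseline_suvr = x, dcdr_sob_per_year = y)
  res <- fit_association(d, "cdr_sob", "baseline_suvr")
  # independent oracle: textbook normal-equations arithmetic
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (6 - 2) / sum((x - mean(x))^2))
  r2 <- 1 - rss / sum((y - mean(y))^2)
  expect_equal(res$coefficient, beta, tolerance = 1e-10)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$r_squared, r2, tolerance = 1e-10)
})

test_that("fit_association is row-order invariant and unit-equivariant", {
  set.seed(41)
  d <- data.frame(baseline_suvr = runif(40, 1.1, 2.5))
  d$davlt_per_year <- -2 * d$baseline_suvr + rnorm(40, 0, 0.5)
  a <- fit_association(d, "avlt")
  b <- fit_association(d[sample(40), ], "avlt")
  expect_equal(a, b)
  d2 <- d; d2$baseline_suvr <- d2$baseline_suvr * 10
  expect_equal(fit_association(d2, "avlt")$coefficient, a$coefficient / 10)
})

test_that("complete-case counts and degenerate inputs behave", {
  d <- data.frame(baseline_suvr = c(1.2, 1.4, 1.6, 1.8, NA),
                  dmmse_per_year = c(0.1, NA, 0.3, 0.2, 0.4))
  res <- fit_association(d, "mmse")
  expect_equal(res$n_used, 3)
  expect_error(fit_association(d[1:2, ], "mmse"), "complete cases")
  d0 <- data.frame(baseline_suvr = rep(1.5, 5), ddrs_per_year = rnorm(5))
  expect_error(fit_association(d0, "drs"), "zero variance")
})

test_that("structural couplings are recovered when channels are isolated", {
  cc_base <- isolated_couplings("base", resid_sd = 0.5)
  cfg <- generator_config(n_cases = 2000, control_pool_size = 0, seed = 11,
                          suvr_noise_sd = 0.001,
                          clinical_couplings = cc_base)
  ann <- annualize(generate_cohort(cfg)$visits)
  tab <- association_table(ann)
  drs <- tab[tab$outcome == "drs" & tab$predictor == "baseline_suvr", ]
  expect_equal(drs$coefficient, -22.40, tolerance = 0.05 * 22.40)
  # every nonzero baseline coupling keeps its sign
  base_rows <- tab[tab$predictor == "baseline_suvr", ]
  truth <- cc_base[match(base_rows$outcome, cc_base$measure), "c_base"]
  expect_true(all(sign(base_rows$coefficient) == sign(truth)))

  cc_rate <- isolated_couplings("rate", resid_sd = 0.3)
  cfg2 <- generator_config(n_cases = 2000, control_pool_size = 0, seed = 12,
                           suvr_noise_sd = 0.001,
                           clinical_couplings = cc_rate)
  ann2 <- annualize(generate_cohort(cfg2)$visits)
  tab2 <- association_table(ann2)
  avlt <- tab2[tab2$outcome == "avlt" & tab2$predictor == "dsuvr_per_year", ]
  expect_equal(avlt$coefficient, -25.05, tolerance = 0.05 * 25.05)
  rate_rows <- tab2[tab2$predictor == "dsuvr_per_year", ]
  truth2 <- cc_rate[match(rate_rows$outcome, cc_rate$measure), "c_rate"]
  expect_true(all(sign(rate_rows$coefficient) == sign(truth2)))
})

test_that("the association table has the full 16-cell layout", {
  cfg <- generator_config(n_cases = 60, control_pool_size = 0, seed = 13)
  ann <- annualize(generate_cohort(cfg)$visits)
  tab <- association_table(ann)
  expect_equal(nrow(tab), 16)
  expect_true(all(is.finite(tab$coefficient)))
  expect_true(all(tab$se > 0))
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
  expect_true(all(tab$n_used <= 60))
})

test_that("null couplings give uniform p values across replicates", {
  cc <- amytraj:::default_couplings()
  for (m in c("mmse", "updrs3", "rcf")) {
    cc[cc$measure == m, c("c_base", "c_rate")] <- 0
  }
  pvals <- matrix(NA_real_, 200, 3, dimnames = list(NULL, c("mmse", "updrs3", "rcf")))
  for (r in 1:200) {
    cfg <- generator_config(n_cases = 40, control_pool_size = 0, seed = 1000 + r,
                            clinical_couplings = cc)
    ann <- annualize(generate_cohort(cfg)$visits)
    for (m in colnames(pvals)) {
      pvals[r, m] <- fit_association(ann, m, "baseline_suvr")$p
    }
  }
  for (m in colnames(pvals)) {
    expect_gt(suppressWarnings(ks.test(pvals[, m], "punif"))$p.value, 0.01)
  }
})

test_that("blocked ANOVA equals the paired-design hand computation", {
  # all equal within every block: no group information at all
  v <- rep(c(5, 5), 3)
  res0 <- compare_groups_blocked(v, rep(c("case", "control"), 3),
                                 rep(1:3, each = 2))
  expect_equal(res0$f_statistic, 0)
  expect_equal(res0$p_value, 1)

  # paired 3-block toy: blocked ANOVA group F must equal the paired t^2
  case_vals <- c(4.1, 5.3, 6.0)
  ctrl_vals <- c(3.0, 3.9, 4.6)
  v <- c(rbind(case_vals, ctrl_vals))
  g <- rep(c("case", "control"), 3)
  b <- rep(1:3, each = 2)
  res <- compare_groups_blocked(v, g, b)
  dbar <- case_vals - ctrl_vals
  t_paired <- mean(dbar) / (sd(dbar) / sqrt(3))
  expect_equal(res$f_statistic, t_paired^2, tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 2)
})

test_that("blocked ANOVA separates the configured group SUVR distributions", {
  set.seed(44)
  p_strong <- 0; p_sig <- 0
  for (r in 1:200) {
    case_suvr <- pmax(rnorm(35, 1.58, 0.41), 1.05)
    ctrl_suvr <- pmax(rnorm(140, 1.36, 0.22), 1.05)
    v <- c(case_suvr, ctrl_suvr)
    g <- c(rep("case", 35), rep("control", 140))
    b <- c(1:35, rep(1:35, each = 4))
    res <- compare_groups_blocked(v, g, b, transform = "log")
    if (res$p_value < 0.001) p_strong <- p_strong + 1
    if (res$p_value < 0.05) p_sig <- p_sig + 1
  }
  # the group F has noncentrality ~3.8 at these means/SDs: essentially
  # always significant, and below 0.001 in the majority of replicates
  expect_gte(p_sig / 200, 0.95)
  expect_gte(p_strong / 200, 0.50)
})

test_that("with a single merged block the test reduces to one-way ANOVA", {
  set.seed(45)
  v <- c(rnorm(10, 1), rnorm(20, 0))
  g <- c(rep("case", 10), rep("control", 20))
  res <- compare_groups_blocked(v, g, rep(1, 30))
  oneway <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(res$f_statistic, oneway[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, oneway[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("incomplete blocks and invalid transforms are refused", {
  v <- c(1, 2, 3)
  expect_error(compare_groups_blocked(v, c("case", "case", "control"),
                                      c(1, 2, 2)), "block")
  expect_error(compare_groups_blocked(c(-1, 1, 2, 3),
                                      rep(c("case", "control"), 2),
                                      rep(1:2, each = 2), transform = "log"),
               "positive")
  expect_error(compare_groups_blocked(c(31, 1, 2, 3),
                                      rep(c("case", "control"), 2),
                                      rep(1:2, each = 2),
                                      transform = "sqrt_reflect",
                                      reflect_at = 30), "exceed")
})
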