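mr_replicates <- function(spec, n_rep, fn) {
  intercept <- calibrate_intercept(spec, 1e5)
  do.call(rbind, lapply(seq_len(n_rep), function(r)
    fn(simulate_mr_population(spec, r, intercept = intercept))))
}

test_that("the full-cohort Wald ratio is consistent for the causal effect", {
  for (beta in c(-0.3, 0, 0.3)) {
    s <- mr_scenario_spec(beta_exposure_progression = beta, seed = 113,
                          n_individuals = 20000)
    est <- mr_replicates(s, 20, function(p) wald_ratio(p, "all"))
    expect_lt(abs(mean(est$estimate) - beta), 4 * mc_se(est$estimate))
  }
})

test_that("without confounders, case selection leaves the Wald ratio unbiased", {
  s <- mr_scenario_spec(beta_exposure_progression = 0.3,
                        beta_c_exposure = 0, beta_u_exposure = 0,
                        seed = 127, n_individuals = 20000)
  # unselected reduced form is the product of the two path coefficients
  expect_equal(expected_mr_case_slope(s, selected = FALSE),
               0.3 * s$beta_instrument_exposure, tolerance = 1e-6)
  # selection attenuates numerator and denominator by the same factor
  # (the only 'confounder' of X is its own noise), so the ratio is intact
  est <- mr_replicates(s, 20, function(p) wald_ratio(p, "cases"))
  expect_lt(abs(mean(est$estimate) - 0.3), 4 * mc_se(est$estimate))
  # and the instrument stays independent of the confounder among cases
  chk <- mr_replicates(s, 20, function(p)
    assumption2_diagnostic(p)[assumption2_diagnostic(p)$stratum == "cases", ])
  expect_lt(abs(mean(chk$estimate)), 4 * mc_se(chk$estimate))
})

test_that("case selection biases the MR estimate of a null effect", {
  s <- mr_scenario_spec(beta_exposure_progression = 0, seed = 131)
  oracle <- expected_mr_case_slope(s)
  expect_lt(oracle, 0)
  intercept <- calibrate_intercept(s, 1e5)
  slopes <- ratios <- a2 <- numeric(40)
  for (r in 1:40) {
    pop <- simulate_mr_population(s, r, intercept = intercept)
    slopes[r] <- case_only_effect(pop, "genotype")$estimate
    ratios[r] <- wald_ratio(pop, "cases")$estimate
    d <- assumption2_diagnostic(pop)
    a2[r] <- d$estimate[d$stratum == "cases"]
  }
  # induced instrument-progression slope matches the quadrature oracle
  expect_lt(abs(mean(slopes) - oracle), 4 * mc_se(slopes))
  expect_lt(mean(slopes) + 4 * mc_se(slopes), 0)
  # hence a nonzero case-only Wald ratio despite a null causal effect
  expect_gt(abs(mean(ratios)), 4 * mc_se(ratios))
  # driven by the induced instrument-confounder association
  expect_gt(abs(mean(a2)), 4 * mc_se(a2))
})

test_that("weak instruments are refused with the first-stage statistic", {
  s <- mr_scenario_spec(beta_instrument_exposure = 0, seed = 137,
                        n_individuals = 5000)
  pop <- simulate_mr_population(s, 1L, intercept = quick_cal(s))
  expect_error(wald_ratio(pop, "all"), "weak instrument.*beta")
})

test_that("run_mr_demo summarizes and flags the selection bias", {
  s <- mr_scenario_spec(beta_exposure_progression = 0, seed = 139,
                        n_individuals = 20000)
  demo <- run_mr_demo(s, n_replicates = 30, calibration_size = 1e5)
  expect_s3_class(demo, "mr_demo")
  expect_true(demo$biased)
  df <- as.data.frame(demo)
  expect_identical(nrow(df), 3L)
  expect_true(all(c("quantity", "mean", "coverage_pct") %in% names(df)))
  full <- df[df$quantity == "wald_ratio_full_cohort", ]
  expect_lt(abs(full$mean), 4 * full$empirical_sd / sqrt(30))
})
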