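test_that("checklist 1 recovers the variant-incidence effect and B's null", {
  s <- scenario_preset("moderate", seed = 61, n_individuals = 100000,
                       include_b = TRUE)
  pop <- quick_pop(s)
  a <- variant_incidence_check(pop, "genotype_a")
  expect_lt(abs(a$estimate - log(1.3)), 4 * a$se)
  b <- variant_incidence_check(pop, "genotype_b")
  expect_lt(abs(b$estimate), 4 * b$se)
})

test_that("checklist 2 finds variant-confounder association only among cases", {
  s <- scenario_preset("strong", seed = 67)
  intercept <- quick_cal(s)
  reps <- lapply(1:30, function(r)
    variant_confounder_check(simulate_population(s, r,
                                                 intercept = intercept)))
  pop_est <- vapply(reps, function(x) x$estimate[x$stratum == "population"],
                    numeric(1))
  case_est <- vapply(reps, function(x) x$estimate[x$stratum == "cases"],
                     numeric(1))
  # independent by construction in the population
  expect_lt(abs(mean(pop_est)), 4 * mc_se(pop_est))
  # induced negative association among cases, matching the oracle
  oracle <- expected_case_only_slope(s, "genotype_a", response = "c")
  expect_lt(oracle, 0)
  expect_lt(mean(case_est) + 4 * mc_se(case_est), 0)
  expect_lt(abs(mean(case_est) - oracle), 4 * mc_se(case_est))
})

test_that("no incidence effect of C means no induced A-C association in cases", {
  s <- scenario_spec(or_c_incidence = 1, or_u_incidence = 3,
                     beta_u_progression = 1.5, n_individuals = 50000,
                     seed = 71)
  chk <- variant_confounder_check(quick_pop(s))
  i <- chk$stratum == "cases"
  expect_lt(abs(chk$estimate[i]), 4 * chk$se[i])
  expect_equal(expected_case_only_slope(s, "genotype_a", response = "c"), 0,
               tolerance = 1e-10)
})

test_that("adjustment for C removes the bias exactly when U confounding is absent", {
  # all incidence-progression confounding runs through measured C
  s_c <- scenario_spec(or_u_incidence = 1, beta_u_progression = 0,
                       or_c_incidence = 2, beta_c_progression = 0.5,
                       n_individuals = 20000, seed = 73)
  expect_equal(expected_case_only_slope(s_c, "genotype_a",
                                        adjust_for = "c"), 0,
               tolerance = 1e-10)
  unadj_oracle <- expected_case_only_slope(s_c, "genotype_a")
  expect_lt(unadj_oracle, 0)
  adj <- replicate_effects(s_c, "genotype_a", 40,
                           fn = adjusted_case_only_effect)
  expect_lt(abs(mean(adj$estimate)), 4 * mc_se(adj$estimate))

  # unmeasured confounding keeps the adjusted estimate biased
  s_u <- scenario_preset("strong", seed = 79, n_individuals = 20000)
  adj_oracle <- expected_case_only_slope(s_u, "genotype_a",
                                         adjust_for = "c")
  expect_lt(adj_oracle, 0)
  adj_u <- replicate_effects(s_u, "genotype_a", 40,
                             fn = adjusted_case_only_effect)
  expect_lt(mean(adj_u$estimate) + 4 * mc_se(adj_u$estimate), 0)
  # and never worsens the bias relative to the unadjusted fit
  expect_lte(abs(adj_oracle),
             abs(expected_case_only_slope(s_u, "genotype_a")) + 1e-12)

  # adjustment leaves the progression-only variant B untouched
  s_b <- scenario_preset("strong", seed = 83, include_b = TRUE,
                         n_individuals = 20000)
  intercept <- quick_cal(s_b)
  b_est <- do.call(rbind, lapply(1:40, function(r) {
    pop <- simulate_population(s_b, r, intercept = intercept)
    rbind(case_only_effect(pop, "genotype_b"),
          adjusted_case_only_effect(pop, "genotype_b"))
  }))
  unadj <- b_est$estimate[seq(1, nrow(b_est), 2)]
  adj <- b_est$estimate[seq(2, nrow(b_est), 2)]
  expect_lt(abs(mean(unadj) - 0.1), 4 * mc_se(unadj))
  expect_lt(abs(mean(adj) - 0.1), 4 * mc_se(adj))
})

test_that("constant selection probabilities make IPW identical to the plain fit", {
  s <- scenario_spec(or_a_incidence = 1, or_c_incidence = 1,
                     or_u_incidence = 1, n_individuals = 10000, seed = 89)
  pop <- quick_pop(s)
  ipw <- ipw_case_only_effect(pop, "genotype_a", "true_probabilities")
  plain <- case_only_effect(pop, "genotype_a")
  expect_equal(ipw$estimate, plain$estimate, tolerance = 1e-10)
  expect_equal(ipw$se, plain$se, tolerance = 1e-10)
})

test_that("IPW with true selection probabilities removes the collider bias", {
  s <- scenario_preset("strong", seed = 97, n_individuals = 20000)
  ipw <- replicate_effects(s, "genotype_a", 40, fn = ipw_case_only_effect,
                           weight_source = "true_probabilities",
                           max_weight_ratio = Inf)
  expect_lt(abs(mean(ipw$estimate)), 4 * mc_se(ipw$estimate))
  ipw_c <- replicate_effects(s, "c", 40, fn = ipw_case_only_effect,
                             weight_source = "true_probabilities",
                             max_weight_ratio = Inf)
  expect_lt(abs(mean(ipw_c$estimate) - 0.1), 4 * mc_se(ipw_c$estimate))
})

test_that("IPW weights fitted without U reduce but do not remove the bias", {
  # measured C must carry an appreciable share of the selection effect for
  # the reduction to be visible: here C removes ~1/3 of the induced bias
  s <- scenario_spec(or_c_incidence = 2, beta_c_progression = 0.5,
                     or_u_incidence = 2, beta_u_progression = 0.8,
                     n_individuals = 20000, seed = 101)
  unw <- replicate_effects(s, "genotype_a", 40)
  fitted <- replicate_effects(s, "genotype_a", 40,
                              fn = ipw_case_only_effect,
                              weight_source = "fitted",
                              fit_on = c("genotype_a", "c"),
                              max_weight_ratio = Inf)
  expect_lt(abs(mean(fitted$estimate)), abs(mean(unw$estimate)))
  expect_lt(mean(fitted$estimate) + 4 * mc_se(fitted$estimate), 0)
})

test_that("extreme selection weights warn, and truncation caps them", {
  s <- scenario_preset("strong", seed = 103, n_individuals = 10000)
  pop <- quick_pop(s)
  expect_warning(ipw_case_only_effect(pop, "genotype_a",
                                      max_weight_ratio = 5),
                 "extreme selection weights")
  plain <- suppressWarnings(
    ipw_case_only_effect(pop, "genotype_a", max_weight_ratio = 5))
  trunc <- suppressWarnings(
    ipw_case_only_effect(pop, "genotype_a", max_weight_ratio = 5,
                         truncate = TRUE))
  expect_false(isTRUE(all.equal(plain$estimate, trunc$estimate)))
})

test_that("the diagnostics report covers the four checklist items", {
  s <- scenario_preset("strong", seed = 107)
  d <- suppressWarnings(collider_diagnostics(quick_pop(s)))
  expect_s3_class(d, "collider_diagnostics")
  expect_identical(sort(unique(d$item)), 1:4)
  expect_identical(d$flag[d$item == 1], "warn")  # A truly causes incidence
  expect_true(all(is.finite(d$estimate)))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(d), f, row.names = FALSE)
  expect_identical(nrow(utils::read.csv(f)), nrow(d))
})
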