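test_that("fit_linear matches the normal-equations brute force", {
  # exact fit: slope recovered with zero residual SE
  x <- 1:10
  fit <- fit_linear(2 * x, data.frame(x = x))
  expect_equal(fit$estimate[fit$term == "x"], 2)
  expect_equal(fit$se[fit$term == "x"], 0)
  expect_equal(fit$ci_low, fit$estimate - 1.96 * fit$se)
  expect_equal(fit$ci_high, fit$estimate + 1.96 * fit$se)

  # 10-row fixture against explicit (X'X)^-1 X'y and textbook SEs
  set.seed(1)
  X <- cbind(x1 = rnorm(10), x2 = runif(10))
  y <- 1 + 0.5 * X[, 1] - 2 * X[, 2] + rnorm(10)
  fit <- fit_linear(y, X)
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi) %*% t(Xi) %*% y
  expect_equal(fit$estimate, drop(beta), ignore_attr = TRUE)
  s2 <- sum((y - Xi %*% beta)^2) / (10 - 3)
  expect_equal(fit$se, sqrt(diag(solve(t(Xi) %*% Xi)) * s2),
               ignore_attr = TRUE)

  # independence: slope indistinguishable from zero
  set.seed(2)
  x <- rnorm(20000); y <- rnorm(20000)
  f <- fit_linear(y, data.frame(x = x))
  expect_lt(abs(f$estimate[f$term == "x"]), 4 / sqrt(20000))
})

test_that("robust standard errors match the HC0 sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(5)
  x <- rnorm(200)
  y <- 1 + 0.5 * x + rnorm(200) * (1 + abs(x))  # heteroskedastic
  w <- runif(200, 0.5, 2)
  f <- fit_linear(y, data.frame(x = x), weights = w, robust = TRUE)
  m <- stats::lm(y ~ x, weights = w)
  expect_equal(f$se, sqrt(diag(sandwich::vcovHC(m, type = "HC0"))),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(f$estimate, unname(coef(m)), tolerance = 1e-10)
})

test_that("fit_linear fails loudly on rank deficiency and bad input", {
  x <- rnorm(20)
  expect_error(fit_linear(rnorm(20), cbind(a = x, b = 2 * x)),
               "rank deficient.*\\b(a|b)\\b")
  expect_error(fit_linear(c(1, NA, 3), cbind(x = 1:3)), "missing")
  expect_error(fit_linear(rnorm(20), cbind(x = x),
                          weights = rep(-1, 20)), "positive")
})

test_that("fit_logistic recovers closed-form and generative log odds ratios", {
  # 2x2 table (20,10,10,20): log-OR = log(4)
  x <- rep(c(1, 0), each = 30)
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_equal(fit$estimate[fit$term == "x"], log(4), tolerance = 1e-6)

  # balanced outcome, null covariate
  set.seed(3)
  x <- rnorm(5000); y <- rbinom(5000, 1, 0.5)
  f <- fit_logistic(y, data.frame(x = x))
  i <- f$term == "x"
  expect_lt(abs(f$estimate[i]), 4 * f$se[i])

  # parameter recovery at large n: per-allele OR 1.3
  set.seed(4)
  g <- rbinom(2e5, 2, 0.2)
  y <- rbinom(2e5, 1, expit(-1.5 + log(1.3) * g))
  f <- fit_logistic(y, data.frame(g = g))
  i <- f$term == "g"
  expect_equal(f$estimate[i], log(1.3), tolerance = 4 * f$se[i])

  expect_error(fit_logistic(c(0, 1, 2), cbind(x = 1:3)), "binary")
})

test_that("case-only effect is null when nothing links variant and progression", {
  s <- scenario_spec(or_u_incidence = 1, beta_u_progression = 0,
                     or_c_incidence = 1, beta_c_progression = 0,
                     n_individuals = 50000, seed = 37)
  est <- case_only_effect(quick_pop(s), "genotype_a")
  expect_false(est$degenerate)
  expect_lt(abs(est$estimate), 4 * est$se)
})

test_that("degenerate case sets are flagged, not fitted", {
  s <- scenario_spec(n_individuals = 150, target_prevalence = 0.05,
                     seed = 41)
  pop <- simulate_population(s, 1L, intercept = logit(0.05))
  est <- case_only_effect(pop, "genotype_a")
  expect_true(est$degenerate)
  expect_true(is.na(est$estimate))
})

test_that("summarize_scenario computes coverage by direct counting", {
  rows <- function(est, lo, hi) data.frame(
    term = "x", estimate = est, se = (hi - lo) / (2 * 1.96),
    ci_low = lo, ci_high = hi, n_used = 100)
  # all intervals contain the truth
  all_in <- rbind(rows(0.1, 0.0, 0.2), rows(0.12, 0.05, 0.2))
  expect_equal(summarize_scenario(all_in, 0.1)$coverage_pct, 100)
  # one of two intervals contains the truth
  half <- rbind(rows(0.1, 0.0, 0.2), rows(0.5, 0.4, 0.6))
  s <- summarize_scenario(half, 0.1)
  expect_equal(s$coverage_pct, 50)
  expect_equal(s$mean_coefficient, 0.3)
  expect_equal(s$n_replicates_used, 2L)
  # degenerate rows are dropped and counted
  half$degenerate <- FALSE
  bad <- rows(NA, NA, NA); bad$degenerate <- TRUE
  s2 <- summarize_scenario(rbind(half, bad), 0.1)
  expect_equal(s2$n_replicates_used, 2L)
  expect_equal(s2$n_dropped, 1L)

  expect_error(summarize_scenario(half[0, ], 0.1), "no estimates")
  expect_error(summarize_scenario(half[1, ], 0.1), "at least 2")
})
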