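#' Wald ratio estimate of the exposure effect on progression
#'
#' The single-instrument instrumental-variable estimator: the ratio of the
#' instrument-progression slope to the instrument-exposure slope, with a
#' delta-method standard error, computed either in the full cohort (the
#' unselected benchmark, available only in simulation) or among cases (the
#' stratum a real progression study has).
#'
#' A first-stage Wald statistic |beta_ZX| / se below 3 is treated as a weak
#' instrument and is an error rather than a silently unstable ratio.
#'
#' @param pop an `mr_population` from [simulate_mr_population()].
#' @param among `"all"` or `"cases"`.
#' @return a one-row `effect_estimate` for the exposure effect, with the
#'   first-stage slope attached as attribute `first_stage`.
#' @export
wald_ratio <- function(pop, among = c("all", "cases")) {
  among <- match.arg(among)
  dat <- if (among == "cases") pop[pop$disease == 1L, , drop = FALSE] else pop
  fs_fit <- fit_linear(dat$exposure, as.matrix(dat[, "genotype",
                                                   drop = FALSE]))
  fs <- fs_fit[fs_fit$term == "genotype", ]
  if (!is.finite(fs$se) || fs$se <= 0 || abs(fs$estimate) / fs$se <= 3)
    stop(sprintf(
      "weak instrument: first-stage |beta|/se = %.2f (beta = %.4f, se = %.4f)",
      abs(fs$estimate) / fs$se, fs$estimate, fs$se), call. = FALSE)
  rf_fit <- fit_linear(dat$progression, as.matrix(dat[, "genotype",
                                                      drop = FALSE]))
  rf <- rf_fit[rf_fit$term == "genotype", ]
  est <- rf$estimate / fs$estimate
  se <- sqrt(rf$se^2 / fs$estimate^2 +
               rf$estimate^2 * fs$se^2 / fs$estimate^4)
  out <- .effect_table("exposure (Wald ratio)", est, se, nrow(dat))
  out$stratum <- among
  attr(out, "first_stage") <- fs
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Instrument-confounder diagnostic for MR of progression
#'
#' The second MR assumption requires the instrument to be independent of
#' exposure-outcome confounders. Case selection breaks this when the exposure
#' causes disease: conditioning on disease induces an association between
#' everything upstream of it. This diagnostic regresses a confounder on the
#' instrument in the full cohort and among cases; a case-only association
#' absent from the cohort is the violation.
#'
#' @param pop an `mr_population`.
#' @param confounder confounder column (default the unmeasured `"u"`).
#' @return a two-row `effect_estimate` with a `stratum` column.
#' @export
assumption2_diagnostic <- function(pop, confounder = "u") {
  variant_confounder_check(pop, variant = "genotype", confounder = confounder)
}

#' Monte-Carlo demonstration of collider bias in MR of progression
#'
#' Simulates `n_replicates` cohorts under an [mr_scenario_spec()] and
#' summarizes the Wald ratio in the full cohort versus among cases, plus the
#' case-only instrument-progression slope against its quadrature expectation.
#' With a null causal effect and an exposure that causes disease onset, the
#' full-cohort ratio is centred on the truth while the case-only ratio is
#' not.
#'
#' @param spec an [mr_scenario_spec()].
#' @param n_replicates number of replicates (default from the spec).
#' @param calibration_size forwarded to [calibrate_intercept()].
#' @return an `mr_demo` list with `scenario_summary` objects `full_cohort`
#'   and `case_only` (Wald ratios, truth = the causal effect), the case-only
#'   instrument slope summary `case_slope` with its quadrature expectation
#'   `case_slope_oracle`, and a logical `biased` flagging whether the mean
#'   case-only ratio sits more than 4 Monte-Carlo SEs from the truth.
#' @export
run_mr_demo <- function(spec, n_replicates = spec$n_replicates,
                        calibration_size = 1e6) {
  stopifnot(inherits(spec, "mr_scenario_spec"))
  intercept <- calibrate_intercept(spec, calibration_size)
  full <- cases <- slope <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    pop <- simulate_mr_population(spec, r, intercept = intercept)
    full[[r]] <- wald_ratio(pop, "all")
    cases[[r]] <- wald_ratio(pop, "cases")
    slope[[r]] <- case_only_effect(pop, "genotype")
  }
  truth <- spec$beta_exposure_progression
  s_full <- summarize_scenario(do.call(rbind, full), truth)
  s_case <- summarize_scenario(do.call(rbind, cases), truth)
  s_slope <- summarize_scenario(do.call(rbind, slope),
                                expected_mr_case_slope(spec))
  mc_se <- s_case$empirical_sd / sqrt(s_case$n_replicates_used)
  structure(list(spec = spec, n_replicates = n_replicates,
                 full_cohort = s_full, case_only = s_case,
                 case_slope = s_slope,
                 case_slope_oracle = s_slope$true_value,
                 biased = abs(s_case$mean_coefficient - truth) > 4 * mc_se),
            class = "mr_demo")
}

#' @export
print.mr_demo <- function(x, ...) {
  cat(sprintf(
    "MR progression demo ('%s', %d replicates of n = %d), true effect %.3f\n",
    x$spec$label, x$n_replicates, x$spec$n_individuals,
    x$spec$beta_exposure_progression))
  cat(sprintf("  full-cohort Wald ratio: %.4f (empirical SD %.4f)\n",
              x$full_cohort$mean_coefficient, x$full_cohort$empirical_sd))
  cat(sprintf("  case-only  Wald ratio: %.4f (empirical SD %.4f)%s\n",
              x$case_only$mean_coefficient, x$case_only$empirical_sd,
              if (x$biased) "  <-- biased by case selection" else ""))
  cat(sprintf(
    "  case-only instrument slope: %.4f (quadrature expectation %.4f)\n",
    x$case_slope$mean_coefficient, x$case_slope_oracle))
  invisible(x)
}

#' Summarize an MR demo as a flat data.frame
#'
#' @param x an `mr_demo` from [run_mr_demo()].
#' @param ... unused.
#' @return a data.frame with one row per reported quantity.
#' @export
as.data.frame.mr_demo <- function(x, ...) {
  row <- function(what, s) data.frame(
    quantity = what, mean = s$mean_coefficient, empirical_sd = s$empirical_sd,
    mean_model_se = s$mean_model_se, coverage_pct = s$coverage_pct,
    true_value = s$true_value, n_replicates = s$n_replicates_used)
  rbind(row("wald_ratio_full_cohort", x$full_cohort),
        row("wald_ratio_case_only", x$case_only),
        row("instrument_slope_case_only", x$case_slope))
}
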