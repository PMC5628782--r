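#' Case-only progression effect of a covariate
#'
#' The estimand every progression GWAS actually computes: the linear
#' regression of progression on `target` restricted to cases
#' (`disease == 1`). By default the fit is univariable; `adjust_for` adds
#' covariates (e.g. the measured confounder `"c"`), which blocks the induced
#' path running through those covariates but not paths through unmeasured
#' ones.
#'
#' Degenerate case sets (fewer than 30 cases, or no variation in the target
#' among cases) yield a flagged NA row rather than an error, so replicate
#' loops can drop and count them.
#'
#' @param pop a `population` from [simulate_population()].
#' @param target column name of the covariate of interest (e.g.
#'   `"genotype_a"`, `"c"`).
#' @param adjust_for character vector of adjustment covariates (default none).
#' @return a one-row `effect_estimate` for `target` with an extra logical
#'   column `degenerate`.
#' @seealso [full_cohort_effect()], [adjusted_case_only_effect()],
#'   [ipw_case_only_effect()]
#' @export
case_only_effect <- function(pop, target, adjust_for = character()) {
  .stratum_effect(pop[pop$disease == 1L, , drop = FALSE], target, adjust_for)
}

#' Full-cohort progression effect (simulation-only oracle)
#'
#' Fits the same regression as [case_only_effect()] on the whole simulated
#' cohort, cases and non-cases alike. In real data progression is undefined
#' for non-cases, so this estimate exists only inside the simulation; it
#' serves as the unselected benchmark against which collider bias is
#' measured.
#'
#' @inheritParams case_only_effect
#' @return a one-row `effect_estimate`.
#' @export
full_cohort_effect <- function(pop, target, adjust_for = character()) {
  .stratum_effect(pop, target, adjust_for)
}

.stratum_effect <- function(dat, target, adjust_for = character(),
                            weights = NULL, robust = FALSE) {
  cols <- c(target, adjust_for)
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols))
    stop("unknown covariate(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(dat) < 30L || stats::var(dat[[target]]) == 0) {
    out <- .effect_table(target, NA_real_, NA_real_, nrow(dat))
    out$degenerate <- TRUE
    return(out)
  }
  fit <- fit_linear(dat$progression,
                    as.matrix(dat[, cols, drop = FALSE]), weights = weights,
                    robust = robust)
  out <- fit[fit$term == target, , drop = FALSE]
  out$degenerate <- FALSE
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Summarize replicate estimates of one scenario cell
#'
#' Pools the per-replicate [case_only_effect()] rows for one covariate into
#' the quantities a coverage simulation reports: the mean coefficient, the
#' empirical SD of coefficients across replicates, the mean model-based SE,
#' and the percentage of replicate 95% Wald intervals containing the true
#' value. Degenerate replicates are dropped and counted.
#'
#' @param estimates an `effect_estimate` data.frame of stacked replicate rows
#'   (columns `estimate`, `se`, `ci_low`, `ci_high`, optionally
#'   `degenerate`).
#' @param true_value the generative value of the coefficient.
#' @return a `scenario_summary` list with fields `mean_coefficient`,
#'   `empirical_sd`, `mean_model_se`, `coverage_pct`, `n_replicates_used`,
#'   `n_dropped`, `true_value`.
#' @examples
#' reps <- do.call(rbind, list(
#'   data.frame(term = "x", estimate = 0.10, se = 0.05,
#'              ci_low = 0.00, ci_high = 0.20, n_used = 100),
#'   data.frame(term = "x", estimate = 0.50, se = 0.05,
#'              ci_low = 0.40, ci_high = 0.60, n_used = 100)))
#' summarize_scenario(reps, true_value = 0.1)$coverage_pct  # 50
#' @export
summarize_scenario <- function(estimates, true_value) {
  est <- as.data.frame(estimates)
  if (!nrow(est)) stop("no estimates to summarize", call. = FALSE)
  drop <- if ("degenerate" %in% names(est)) est$degenerate | is.na(est$estimate)
          else is.na(est$estimate)
  est <- est[!drop, , drop = FALSE]
  if (nrow(est) < 2L)
    stop("need at least 2 non-degenerate estimates", call. = FALSE)
  structure(list(
    mean_coefficient = mean(est$estimate),
    empirical_sd = stats::sd(est$estimate),
    mean_model_se = mean(est$se),
    coverage_pct = 100 * mean(est$ci_low <= true_value &
                                true_value <= est$ci_high),
    n_replicates_used = nrow(est),
    n_dropped = sum(drop),
    true_value = true_value),
    class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf(
    "scenario summary (%d replicates, %d dropped)\n  mean coefficient %.4f (true %.3f)\n  empirical SD %.4f | mean model SE %.4f\n  95%% CI coverage of truth: %.1f%%\n",
    x$n_replicates_used, x$n_dropped, x$mean_coefficient, x$true_value,
    x$empirical_sd, x$mean_model_se, x$coverage_pct))
  invisible(x)
}
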