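# True generative progression effect for a covariate label.
.true_progression_effect <- function(spec, target) {
  switch(target,
         genotype_a = spec$beta_a_progression,
         genotype_b = if (spec$include_b) spec$beta_b_progression else 0,
         c = spec$beta_c_progression,
         u = spec$beta_u_progression[1],
         stop("no generative truth defined for target '", target, "'",
              call. = FALSE))
}

#' Run all replicates of one scenario and summarize the case-only estimates
#'
#' Calibrates the incidence intercept once, simulates `n_replicates` cohorts,
#' fits the case-only regression of progression on each target, and pools the
#' replicates with [summarize_scenario()] against each target's generative
#' truth. `joint = TRUE` fits all targets in a single multivariable
#' regression instead of the default separate univariable fits.
#'
#' @param spec a [scenario_spec()].
#' @param targets covariates to estimate (default variant A and measured
#'   confounder C).
#' @param n_replicates number of replicates (default from the spec).
#' @param joint fit targets jointly rather than one univariable model each.
#' @param calibration_size forwarded to [calibrate_intercept()].
#' @return a `scenario_result`: list with the spec, calibrated `intercept`,
#'   mean observed `prevalence` across replicates, per-target
#'   `scenario_summary` list `summaries`, the stacked per-replicate
#'   `estimates`, and `n_dropped` degenerate replicates.
#' @export
run_scenario <- function(spec, targets = c("genotype_a", "c"),
                         n_replicates = spec$n_replicates, joint = FALSE,
                         calibration_size = 1e6) {
  validate_scenario_spec(spec)
  intercept <- calibrate_intercept(spec, calibration_size)
  rows <- vector("list", n_replicates)
  prev <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    pop <- simulate_population(spec, r, intercept = intercept)
    prev[r] <- mean(pop$disease)
    ests <- lapply(targets, function(tg)
      case_only_effect(pop, tg,
                       adjust_for = if (joint) setdiff(targets, tg)
                                    else character()))
    est <- do.call(rbind, ests)
    est$replicate <- r
    rows[[r]] <- est
  }
  estimates <- do.call(rbind, rows)
  summaries <- lapply(stats::setNames(targets, targets), function(tg)
    summarize_scenario(estimates[estimates$term == tg, ],
                       .true_progression_effect(spec, tg)))
  structure(list(spec = spec, intercept = intercept,
                 prevalence = mean(prev), summaries = summaries,
                 estimates = estimates,
                 n_dropped = summaries[[1]]$n_dropped),
            class = "scenario_result")
}

#' Reproduce the four-scenario bias/coverage table
#'
#' Runs the four confounding presets (low, moderate, high, strong) at
#' `n_replicates` replicates of `n_individuals` each and tabulates, for the
#' incidence-only variant A and the shared risk factor C: the mean case-only
#' coefficient, the mean model SE, the empirical SD, and the percentage of
#' 95% Wald intervals containing the generative truth (0 for A, 0.1 for C).
#' Fully reproducible from `seed`; per-preset seeds derive deterministically
#' from it.
#'
#' @param seed master seed.
#' @param n_replicates replicates per preset (500 for the full table; 200 is
#'   a desk-scale run).
#' @param n_individuals cohort size per replicate.
#' @param residual_sd progression noise SD (see [scenario_spec()]).
#' @param presets preset labels to run.
#' @param joint fit A and C jointly instead of univariably.
#' @param calibration_size forwarded to [calibrate_intercept()].
#' @return a `table1_report`: a long data.frame (one row per preset x target)
#'   with columns `scenario`, `or_u_incidence`, `beta_u_progression`,
#'   `target`, `true_value`, `mean_coefficient`, `mean_model_se`,
#'   `empirical_sd`, `coverage_pct`, `prevalence`, `n_replicates_used`,
#'   `n_dropped`, plus run metadata in attributes (`seed`, `n_replicates`,
#'   `n_individuals`, `residual_sd`, `runtime_sec`).
#' @examples
#' \donttest{
#' rep <- run_table1(seed = 1, n_replicates = 5, n_individuals = 5000,
#'                   calibration_size = 1e5)
#' print(rep)
#' }
#' @export
run_table1 <- function(seed = 1L, n_replicates = 500L,
                       n_individuals = 50000L, residual_sd = 0.7,
                       presets = c("low", "moderate", "high", "strong"),
                       joint = FALSE, calibration_size = 1e6) {
  t0 <- proc.time()[["elapsed"]]
  rows <- list()
  for (i in seq_along(presets)) {
    spec <- scenario_preset(presets[i],
                            seed = derive_seed(seed, i, stream = 2L),
                            n_individuals = n_individuals,
                            n_replicates = n_replicates,
                            residual_sd = residual_sd)
    res <- tryCatch(
      run_scenario(spec, n_replicates = n_replicates, joint = joint,
                   calibration_size = calibration_size),
      error = function(e) stop("preset '", presets[i], "' failed: ",
                               conditionMessage(e), call. = FALSE))
    for (tg in names(res$summaries)) {
      s <- res$summaries[[tg]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = presets[i],
        or_u_incidence = spec$or_u_incidence,
        beta_u_progression = spec$beta_u_progression,
        target = tg, true_value = s$true_value,
        mean_coefficient = s$mean_coefficient,
        mean_model_se = s$mean_model_se,
        empirical_sd = s$empirical_sd,
        coverage_pct = s$coverage_pct,
        prevalence = res$prevalence,
        n_replicates_used = s$n_replicates_used,
        n_dropped = s$n_dropped)
    }
  }
  structure(do.call(rbind, rows),
            class = c("table1_report", "data.frame"),
            seed = seed, n_replicates = n_replicates,
            n_individuals = n_individuals, residual_sd = residual_sd,
            joint = joint,
            runtime_sec = proc.time()[["elapsed"]] - t0)
}

#' Format a bias/coverage report as a markdown table
#'
#' Lays the long report out like the printed reference table: one column per
#' confounding scenario, row groups for the apparent effect of A (mean
#' coefficient with mean SE, 2 decimals) and its CI coverage of 0 (whole
#' percent), then the same for C against 0.1.
#'
#' @param report a `table1_report`.
#' @return character vector of markdown lines.
#' @export
format_table1 <- function(report) {
  stopifnot(inherits(report, "table1_report"))
  scen <- unique(report$scenario)
  cell <- function(target, what) vapply(scen, function(s) {
    r <- report[report$scenario == s & report$target == target, ]
    switch(what,
           effect = sprintf("%.2f (%.2f)", r$mean_coefficient,
                            r$mean_model_se),
           coverage = sprintf("%.0f%%", r$coverage_pct))
  }, character(1))
  hdr <- report[report$target == report$target[1], ]
  lines <- c(
    paste0("| Simulated scenario | ",
           paste(sprintf("%s (OR = %g, beta = %g)", scen,
                         hdr$or_u_incidence, hdr$beta_u_progression),
                 collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(scen) + 1), collapse = "|"), "|"),
    paste0("| Apparent effect of A on progression (true 0) | ",
           paste(cell("genotype_a", "effect"), collapse = " | "), " |"),
    paste0("| Percentage of 95% CI including 0 | ",
           paste(cell("genotype_a", "coverage"), collapse = " | "), " |"),
    paste0("| Apparent effect of C on progression (true 0.1) | ",
           paste(cell("c", "effect"), collapse = " | "), " |"),
    paste0("| Percentage of 95% CI including 0.1 | ",
           paste(cell("c", "coverage"), collapse = " | "), " |"))
  meta <- sprintf(
    "%d replicates of n = %d per scenario; seed %d; residual SD %.2f; %d degenerate replicates dropped.",
    attr(report, "n_replicates"), attr(report, "n_individuals"),
    attr(report, "seed"), attr(report, "residual_sd"),
    sum(report$n_dropped[report$target == report$target[1]]))
  c(lines, "", meta)
}

#' Write a bias/coverage report to disk
#'
#' CSV output is the long data.frame at full precision (RFC 4180, no
#' quoting needed); markdown output is [format_table1()].
#'
#' @param report a `table1_report`.
#' @param path output path (extension added when `format` is given a single
#'   value and `path` has none).
#' @param format `"csv"`, `"md"`, or both.
#' @return the paths written, invisibly.
#' @export
write_table1 <- function(report, path, format = c("csv", "md")) {
  format <- match.arg(format, several.ok = TRUE)
  base <- sub("\\.(csv|md)$", "", path)
  written <- character(0)
  if ("csv" %in% format) {
    f <- paste0(base, ".csv")
    utils::write.csv(as.data.frame(report), f, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, f)
  }
  if ("md" %in% format) {
    f <- paste0(base, ".md")
    writeLines(format_table1(report), f)
    written <- c(written, f)
  }
  invisible(written)
}

#' @export
print.table1_report <- function(x, ...) {
  cat(format_table1(x), sep = "\n")
  cat(sprintf("(runtime %.1f s)\n", attr(x, "runtime_sec")))
  invisible(x)
}
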