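#' Define a confounding scenario for the incidence/progression simulator
#'
#' A `scenario_spec` holds every generative parameter of one synthetic cohort:
#' a biallelic variant A acting on disease incidence only, an optional variant
#' B acting on progression only, a measured standard-normal confounder C and
#' one or more unmeasured standard-normal confounders U acting on both
#' incidence and progression. Disease is Bernoulli with a logistic incidence
#' model whose intercept is calibrated to `target_prevalence`
#' (see [calibrate_intercept()]); progression is a normal variable generated
#' for everyone but, by design, observed only among cases.
#'
#' Odds ratios are per allele (variants) or per standard deviation
#' (confounders); progression effects are on the raw progression scale.
#' `or_u_incidence` and `beta_u_progression` may be vectors of equal length to
#' model several independent unmeasured confounders; the default is one.
#'
#' @param label scenario name; the four built-in presets are
#'   `"low"`, `"moderate"`, `"high"`, `"strong"` (see [scenario_preset()]).
#' @param n_individuals cohort size per replicate (>= 100).
#' @param n_replicates default number of Monte-Carlo replicates.
#' @param maf_a,maf_b minor allele frequencies in (0, 1).
#' @param or_a_incidence per-allele incidence odds ratio of variant A.
#' @param beta_a_progression progression effect of A (0 = true null).
#' @param include_b whether to generate the progression-only variant B.
#' @param beta_b_progression progression effect per B allele (used when
#'   `include_b = TRUE`).
#' @param or_c_incidence,beta_c_progression effects of the measured
#'   confounder C on incidence (OR per SD) and progression.
#' @param or_u_incidence,beta_u_progression effects of the unmeasured
#'   confounder(s) U; equal-length vectors.
#' @param target_prevalence marginal disease probability in (0, 1).
#' @param residual_sd SD of progression noise. The default 0.7 is calibrated
#'   so that at roughly 10,000 cases the model-based standard errors of the
#'   case-only fits fall in the 0.01-0.03 (variant) and 0.01-0.02
#'   (confounder) range typical of this design.
#' @param seed master seed; all replicate and calibration seeds derive from
#'   it deterministically.
#' @return an object of class `scenario_spec`.
#' @seealso [scenario_preset()], [simulate_population()], [run_table1()]
#' @examples
#' spec <- scenario_spec(or_u_incidence = 2, beta_u_progression = 0.8,
#'                       n_individuals = 5000, seed = 1)
#' spec
#' @export
scenario_spec <- function(label = "custom",
                          n_individuals = 50000L,
                          n_replicates = 500L,
                          maf_a = 0.2,
                          or_a_incidence = 1.3,
                          beta_a_progression = 0,
                          include_b = FALSE,
                          maf_b = 0.2,
                          beta_b_progression = 0.1,
                          or_c_incidence = 1.3,
                          beta_c_progression = 0.1,
                          or_u_incidence = 1.5,
                          beta_u_progression = 0.5,
                          target_prevalence = 0.2,
                          residual_sd = 0.7,
                          seed = 1L) {
  spec <- structure(
    list(label = as.character(label),
         n_individuals = as.integer(n_individuals),
         n_replicates = as.integer(n_replicates),
         maf_a = maf_a, or_a_incidence = or_a_incidence,
         beta_a_progression = beta_a_progression,
         include_b = isTRUE(include_b), maf_b = maf_b,
         beta_b_progression = beta_b_progression,
         or_c_incidence = or_c_incidence,
         beta_c_progression = beta_c_progression,
         or_u_incidence = or_u_incidence,
         beta_u_progression = beta_u_progression,
         target_prevalence = target_prevalence,
         residual_sd = residual_sd,
         seed = as.integer(seed)),
    class = "scenario_spec")
  validate_scenario_spec(spec)
}

validate_scenario_spec <- function(spec) {
  stopifnot(is.list(spec))
  if (spec$n_individuals < 100)
    stop("n_individuals must be >= 100", call. = FALSE)
  if (spec$n_replicates < 1)
    stop("n_replicates must be positive", call. = FALSE)
  ors <- c(spec$or_a_incidence, spec$or_c_incidence, spec$or_u_incidence,
           spec$or_exposure_incidence)
  if (any(ors <= 0))
    stop("all odds ratios must be > 0", call. = FALSE)
  mafs <- c(spec$maf_a, spec$maf_b, spec$maf_instrument)
  if (any(mafs <= 0 | mafs >= 1))
    stop("allele frequencies must lie in (0, 1)", call. = FALSE)
  if (spec$target_prevalence <= 0 || spec$target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)", call. = FALSE)
  if (spec$residual_sd <= 0)
    stop("residual_sd must be positive", call. = FALSE)
  if (length(spec$or_u_incidence) != length(spec$beta_u_progression))
    stop("or_u_incidence and beta_u_progression must have equal length",
         call. = FALSE)
  spec
}

# (OR per SD of U on incidence, effect of U on progression) for the four
# named degrees of unmeasured confounding.
.preset_table <- list(
  low      = c(or_u = 1.5, beta_u = 0.5),
  moderate = c(or_u = 2.0, beta_u = 0.8),
  high     = c(or_u = 2.5, beta_u = 1.0),
  strong   = c(or_u = 3.0, beta_u = 1.5)
)

#' Built-in confounding presets
#'
#' The four degrees of unmeasured confounding studied in the package's
#' reference simulation: U's incidence odds ratio per SD is 1.5 / 2 / 2.5 / 3
#' and its progression effect 0.5 / 0.8 / 1 / 1.5 for the `low`, `moderate`,
#' `high` and `strong` presets. All other parameters keep the
#' [scenario_spec()] defaults unless overridden through `...`.
#'
#' @param label one of `"low"`, `"moderate"`, `"high"`, `"strong"`.
#' @param ... overrides passed on to [scenario_spec()] (e.g. `seed`,
#'   `n_individuals`).
#' @return a `scenario_spec`.
#' @examples
#' scenario_preset("strong", seed = 7)
#' @export
scenario_preset <- function(label = c("low", "moderate", "high", "strong"),
                            ...) {
  label <- match.arg(label)
  p <- .preset_table[[label]]
  args <- list(...)
  if (any(c("or_u_incidence", "beta_u_progression") %in% names(args)))
    stop("preset fixes or_u_incidence and beta_u_progression; ",
         "use scenario_spec() for custom values", call. = FALSE)
  do.call(scenario_spec,
          c(list(label = label, or_u_incidence = unname(p["or_u"]),
                 beta_u_progression = unname(p["beta_u"])), args))
}

#' Define a Mendelian-randomization progression scenario
#'
#' Extends the incidence/progression DAG with an exposure X instrumented by a
#' genetic variant Z: `X = beta_instrument_exposure * Z + beta_c_exposure * C
#' + beta_u_exposure * U + noise`, incidence depends on X (OR per SD of X) and
#' optionally directly on C and U, and progression depends on X (the causal
#' effect of interest), C and U. Selecting cases opens a collider path from Z
#' to the confounders of X and progression, violating the MR assumption that
#' the instrument is independent of exposure-outcome confounders.
#'
#' The numeric defaults are illustrative, not a reproduction of any published
#' parameter set: a common variant (MAF 0.3) explaining a few percent of
#' exposure variance, an exposure with a strong incidence effect (OR 2.5 per
#' unit), and confounders acting on exposure and progression but not directly
#' on incidence (their incidence effect flows through the exposure). They are
#' deliberately strong enough that the induced case-only bias is clearly
#' resolvable in a few dozen replicates.
#'
#' @param label scenario name.
#' @param maf_instrument instrument allele frequency.
#' @param beta_instrument_exposure per-allele effect of Z on X.
#' @param exposure_sd SD of the exposure noise term.
#' @param beta_exposure_progression true causal effect of X on progression
#'   (0 = null).
#' @param or_exposure_incidence incidence odds ratio per unit of X.
#' @param beta_c_exposure,beta_u_exposure confounder effects on the exposure.
#' @param or_c_incidence,or_u_incidence direct confounder effects on
#'   incidence (default 1: none; incidence confounding runs through X).
#' @param beta_c_progression,beta_u_progression confounder effects on
#'   progression.
#' @param n_individuals,n_replicates,target_prevalence,residual_sd,seed as in
#'   [scenario_spec()].
#' @return an object of class `mr_scenario_spec` (inherits `scenario_spec`).
#' @seealso [simulate_mr_population()], [wald_ratio()], [run_mr_demo()]
#' @export
mr_scenario_spec <- function(label = "mr",
                             n_individuals = 50000L,
                             n_replicates = 200L,
                             maf_instrument = 0.3,
                             beta_instrument_exposure = 0.3,
                             exposure_sd = 0.8,
                             beta_exposure_progression = 0,
                             or_exposure_incidence = 2.5,
                             beta_c_exposure = 0.3,
                             beta_c_progression = 0.1,
                             or_c_incidence = 1,
                             beta_u_exposure = 0.8,
                             beta_u_progression = 1.0,
                             or_u_incidence = 1,
                             target_prevalence = 0.2,
                             residual_sd = 0.7,
                             seed = 1L) {
  spec <- structure(
    list(label = as.character(label),
         n_individuals = as.integer(n_individuals),
         n_replicates = as.integer(n_replicates),
         maf_instrument = maf_instrument,
         beta_instrument_exposure = beta_instrument_exposure,
         exposure_sd = exposure_sd,
         beta_exposure_progression = beta_exposure_progression,
         or_exposure_incidence = or_exposure_incidence,
         beta_c_exposure = beta_c_exposure,
         beta_c_progression = beta_c_progression,
         or_c_incidence = or_c_incidence,
         beta_u_exposure = beta_u_exposure,
         beta_u_progression = beta_u_progression,
         or_u_incidence = or_u_incidence,
         target_prevalence = target_prevalence,
         residual_sd = residual_sd,
         seed = as.integer(seed)),
    class = c("mr_scenario_spec", "scenario_spec"))
  if (spec$exposure_sd <= 0)
    stop("exposure_sd must be positive", call. = FALSE)
  validate_scenario_spec(spec)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<%s> scenario '%s': n = %d, replicates = %d, seed = %d\n",
              class(x)[1], x$label, x$n_individuals, x$n_replicates, x$seed))
  show <- setdiff(names(x), c("label", "n_individuals", "n_replicates",
                              "seed"))
  for (f in show)
    cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  invisible(x)
}

#' Read a scenario from a structured config file
#'
#' The config is YAML whose keys are exactly the argument names of
#' [scenario_spec()] (or of [mr_scenario_spec()] when an exposure field such
#' as `maf_instrument` is present). Unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return a `scenario_spec` or `mr_scenario_spec`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a mapping of scenario fields", call. = FALSE)
  ctor <- if (any(c("maf_instrument", "beta_instrument_exposure",
                    "or_exposure_incidence") %in% names(cfg)))
    mr_scenario_spec else scenario_spec
  bad <- setdiff(names(cfg), names(formals(ctor)))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(ctor, cfg)
}
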