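#' Simulate one replicate cohort under the incidence/progression DAG
#'
#' Generates `n_individuals` with genotype A ~ Binomial(2, maf), independent
#' standard-normal C and U, disease ~ Bernoulli(expit(alpha + log(OR_A) A +
#' log(OR_C) C + log(OR_U) U)) with `alpha` calibrated to the target
#' prevalence, and progression = beta_A A (+ beta_B B when enabled) +
#' beta_C C + beta_U U +
#' Normal(0, residual_sd^2). Progression is generated for everyone; analyses
#' of real case-only designs see it only among cases, so full-cohort fits on
#' this object are a simulation-only oracle.
#'
#' The per-replicate RNG seed derives deterministically from
#' `(spec$seed, replicate)`, so any replicate can be regenerated in isolation
#' and identical inputs give bit-identical cohorts.
#'
#' A replicate with fewer than 30 cases or no genotype variation among cases
#' is flagged degenerate (`attr(pop, "degenerate")`); summary functions drop
#' and count such replicates.
#'
#' @param spec a [scenario_spec()].
#' @param replicate replicate index (1-based).
#' @param intercept calibrated incidence intercept; if `NULL` it is computed
#'   via [calibrate_intercept()] (pass it explicitly when simulating many
#'   replicates to calibrate once).
#' @param calibration_size forwarded to [calibrate_intercept()] when
#'   `intercept` is `NULL`.
#' @return a `population`: a data.frame with columns `id`, `genotype_a`,
#'   `genotype_b` (NA unless `include_b`), `c`, `u` (plus `u2`, ... for
#'   multiple unmeasured confounders), `disease`, `progression` and
#'   `incidence_probability` (the true selection probability, retained for
#'   oracle inverse-probability weighting), with the spec, replicate index,
#'   intercept and degeneracy flag as attributes.
#' @examples
#' pop <- simulate_population(scenario_preset("low", n_individuals = 2000),
#'                            replicate = 1, calibration_size = 1e5)
#' mean(pop$disease)
#' @export
simulate_population <- function(spec, replicate = 1L, intercept = NULL,
                                calibration_size = 1e6) {
  validate_scenario_spec(spec)
  if (inherits(spec, "mr_scenario_spec"))
    stop("use simulate_mr_population() for an mr_scenario_spec", call. = FALSE)
  if (is.null(intercept))
    intercept <- calibrate_intercept(spec, calibration_size)
  set.seed(derive_seed(spec$seed, as.integer(replicate), stream = 0L))
  n <- spec$n_individuals
  g <- stats::rbinom(n, 2L, spec$maf_a)
  cc <- stats::rnorm(n)
  nu <- length(spec$or_u_incidence)
  u <- matrix(stats::rnorm(n * nu), n, nu)
  b <- if (spec$include_b) stats::rbinom(n, 2L, spec$maf_b) else NULL

  p <- expit(intercept + log(spec$or_a_incidence) * g +
               log(spec$or_c_incidence) * cc +
               drop(u %*% log(spec$or_u_incidence)))
  disease <- stats::rbinom(n, 1L, p)
  progression <- spec$beta_a_progression * g +
    spec$beta_c_progression * cc +
    drop(u %*% spec$beta_u_progression) +
    stats::rnorm(n, 0, spec$residual_sd)
  if (!is.null(b)) progression <- progression + spec$beta_b_progression * b

  pop <- data.frame(id = seq_len(n), genotype_a = g,
                    genotype_b = if (is.null(b)) NA_integer_ else b,
                    c = cc, u = u[, 1], disease = disease,
                    progression = progression, incidence_probability = p)
  if (nu > 1L)
    for (j in 2:nu) pop[[paste0("u", j)]] <- u[, j]
  .as_population(pop, spec, replicate, intercept)
}

#' Simulate one replicate cohort under the MR progression DAG
#'
#' As [simulate_population()], but with an instrumented exposure: the variant
#' Z affects a continuous exposure X, X (and optionally the confounders
#' directly) affects incidence on the odds-ratio scale, and progression
#' depends on X, C and U. Conditioning on disease induces an association
#' between Z and the confounders of the exposure-progression relationship.
#'
#' @param spec an [mr_scenario_spec()].
#' @inheritParams simulate_population
#' @return an `mr_population` data.frame with columns `id`, `genotype`,
#'   `exposure`, `c`, `u`, `disease`, `progression`,
#'   `incidence_probability`.
#' @export
simulate_mr_population <- function(spec, replicate = 1L, intercept = NULL,
                                   calibration_size = 1e6) {
  stopifnot(inherits(spec, "mr_scenario_spec"))
  if (is.null(intercept))
    intercept <- calibrate_intercept(spec, calibration_size)
  set.seed(derive_seed(spec$seed, as.integer(replicate), stream = 0L))
  n <- spec$n_individuals
  g <- stats::rbinom(n, 2L, spec$maf_instrument)
  cc <- stats::rnorm(n)
  u <- stats::rnorm(n)
  x <- spec$beta_instrument_exposure * g + spec$beta_c_exposure * cc +
    spec$beta_u_exposure * u + stats::rnorm(n, 0, spec$exposure_sd)
  p <- expit(intercept + log(spec$or_exposure_incidence) * x +
               log(spec$or_c_incidence) * cc + log(spec$or_u_incidence) * u)
  disease <- stats::rbinom(n, 1L, p)
  progression <- spec$beta_exposure_progression * x +
    spec$beta_c_progression * cc + spec$beta_u_progression * u +
    stats::rnorm(n, 0, spec$residual_sd)

  pop <- data.frame(id = seq_len(n), genotype = g, exposure = x, c = cc,
                    u = u, disease = disease, progression = progression,
                    incidence_probability = p)
  out <- .as_population(pop, spec, replicate, intercept,
                        genotype_col = "genotype")
  class(out) <- c("mr_population", class(out))
  out
}

.as_population <- function(pop, spec, replicate, intercept,
                           genotype_col = "genotype_a") {
  n_cases <- sum(pop$disease)
  degenerate <- n_cases < 30L ||
    stats::var(pop[[genotype_col]][pop$disease == 1L]) == 0
  structure(pop,
            class = c("population", "data.frame"),
            spec = spec, replicate = as.integer(replicate),
            intercept = intercept, degenerate = degenerate)
}

#' Number of cases in a simulated population
#' @param pop a `population`.
#' @return integer case count.
#' @export
n_cases <- function(pop) sum(pop$disease == 1L)

#' Was the replicate degenerate?
#'
#' A replicate is degenerate when it has fewer than 30 cases or no genotype
#' variation among cases; such replicates are excluded from scenario
#' summaries with a logged count.
#'
#' @param pop a `population`.
#' @return logical.
#' @export
is_degenerate <- function(pop) isTRUE(attr(pop, "degenerate"))

#' Export a population to CSV
#'
#' Writes the flat interop layout `id, genotype_a, genotype_b, c, u, disease,
#' progression` (or `id, genotype, exposure, c, u, disease, progression` for
#' MR cohorts); the internal true incidence probability is not exported.
#'
#' @param pop a `population`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  keep <- setdiff(names(pop), "incidence_probability")
  utils::write.csv(as.data.frame(pop)[keep], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
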