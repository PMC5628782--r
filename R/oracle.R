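# Gauss-Hermite nodes/weights rescaled for a standard normal variable:
# E[f(Z)] = sum(w * f(z)).
.gh_normal <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Cell grid over (genotype, C, U) with base (unselected) probabilities.
# Single unmeasured confounder only: the quadrature oracle is defined for
# the one-U design.
.quad_grid <- function(spec, nodes) {
  if (length(spec$or_u_incidence) != 1L)
    stop("the quadrature oracle supports a single unmeasured confounder",
         call. = FALSE)
  gh <- .gh_normal(nodes)
  g <- 0:2
  pg <- stats::dbinom(g, 2, spec$maf_a)
  grid <- expand.grid(g = g, c = gh$z, u = gh$z, KEEP.OUT.ATTRS = FALSE)
  wc <- gh$w[match(grid$c, gh$z)]
  wu <- gh$w[match(grid$u, gh$z)]
  grid$w <- pg[grid$g + 1L] * wc * wu
  grid$eta <- log(spec$or_a_incidence) * grid$g +
    log(spec$or_c_incidence) * grid$c + log(spec$or_u_incidence) * grid$u
  grid
}

.quad_intercept <- function(grid, target_prevalence) {
  f <- function(a) sum(grid$w * expit(a + grid$eta)) - target_prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Expected marginal prevalence by quadrature
#'
#' Deterministic Gauss-Hermite evaluation of the marginal disease
#' probability under a scenario; the independent cross-check for the
#' Monte-Carlo intercept calibration.
#'
#' @param spec a single-U [scenario_spec()].
#' @param intercept incidence intercept; if `NULL`, the quadrature's own
#'   root-found intercept is used (in which case the result is the target
#'   prevalence by construction).
#' @param nodes Gauss-Hermite nodes per normal dimension.
#' @return expected prevalence (scalar).
#' @export
expected_prevalence <- function(spec, intercept = NULL, nodes = 48) {
  grid <- .quad_grid(spec, nodes)
  if (is.null(intercept))
    intercept <- .quad_intercept(grid, spec$target_prevalence)
  sum(grid$w * expit(intercept + grid$eta))
}

.quad_slope_once <- function(spec, target, adjust_for, selected, nodes,
                             response = "progression") {
  grid <- .quad_grid(spec, nodes)
  w <- grid$w
  if (selected) {
    alpha <- .quad_intercept(grid, spec$target_prevalence)
    w <- w * expit(alpha + grid$eta)
  }
  w <- w / sum(w)
  cols <- list(genotype_a = grid$g, c = grid$c, u = grid$u)
  y <- if (response == "progression") {
    spec$beta_a_progression * grid$g +
      spec$beta_c_progression * grid$c + spec$beta_u_progression * grid$u
  } else if (response %in% names(cols)) {
    cols[[response]]
  } else stop("unknown oracle response '", response, "'", call. = FALSE)
  vars <- c(target, adjust_for)
  if (!all(vars %in% names(cols)))
    stop("oracle targets must be among: ", paste(names(cols), collapse = ", "),
         call. = FALSE)
  V <- cbind(1, do.call(cbind, cols[vars]))
  beta <- solve(crossprod(V, V * w), crossprod(V, y * w))
  beta[1 + match(target, vars)]
}

#' Expected case-only regression slope (quadrature oracle)
#'
#' Computes, without any Monte-Carlo simulation, the population value that
#' the (possibly adjusted) case-only least-squares slope converges to:
#' genotype is enumerated, the confounders are integrated by Gauss-Hermite
#' quadrature, each cell is weighted by its probability times (when
#' `selected`) the calibrated probability of disease, and the weighted
#' least-squares projection of the conditional mean of progression on the
#' target (plus adjustments) is solved in closed form. Serves as the
#' independent oracle against which the simulation means are checked.
#'
#' The result is computed at `nodes` and at `2 * nodes` Gauss-Hermite nodes;
#' a change above `1e-3` between refinements is an error asking for a finer
#' grid.
#'
#' The progression-only variant B is independent of all selection variables,
#' so its expected univariable slope is its generative effect (returned
#' analytically, 0 when B is disabled).
#'
#' @param spec a single-U [scenario_spec()].
#' @param target `"genotype_a"`, `"c"`, `"u"` or `"genotype_b"`.
#' @param adjust_for covariates partialled out (subset of
#'   `c("genotype_a", "c", "u")`).
#' @param selected if `TRUE` (default) weight by case selection; if `FALSE`
#'   return the unselected whole-population projection.
#' @param nodes base Gauss-Hermite resolution per normal dimension.
#' @param response regressand: `"progression"` (default), or a covariate
#'   (e.g. `response = "c", target = "genotype_a"` gives the expected
#'   variant-confounder slope induced by selection).
#' @return expected slope (scalar).
#' @examples
#' s <- scenario_preset("strong")
#' expected_case_only_slope(s, "genotype_a")  # negative: induced bias
#' expected_case_only_slope(s, "c", selected = FALSE)  # 0.1: no selection
#' @export
expected_case_only_slope <- function(spec, target = "genotype_a",
                                     adjust_for = character(),
                                     selected = TRUE, nodes = 48,
                                     response = "progression") {
  validate_scenario_spec(spec)
  if (target == "genotype_b") {
    if (length(adjust_for))
      stop("the analytic B slope is univariable only", call. = FALSE)
    return(if (spec$include_b && response == "progression")
             spec$beta_b_progression else 0)
  }
  coarse <- .quad_slope_once(spec, target, adjust_for, selected, nodes,
                             response)
  fine <- .quad_slope_once(spec, target, adjust_for, selected, 2L * nodes,
                           response)
  if (abs(fine - coarse) > 1e-3)
    stop(sprintf(
      "quadrature grid too coarse: slope changed by %.2g on refinement; increase nodes (used %d)",
      abs(fine - coarse), nodes), call. = FALSE)
  fine
}

#' Expected case-only instrument-progression slope in the MR design
#'
#' Quadrature analogue of [expected_case_only_slope()] for the
#' instrumented-exposure DAG: the exposure's own noise adds a third normal
#' dimension to the Gauss-Hermite grid. Returns the expected univariable
#' case-only slope of progression on the instrument, i.e. the numerator bias
#' an MR analysis of progression inherits from case selection.
#'
#' @param spec an [mr_scenario_spec()].
#' @param selected weight by case selection (default) or not.
#' @param nodes Gauss-Hermite resolution per normal dimension.
#' @return expected slope (scalar).
#' @export
expected_mr_case_slope <- function(spec, selected = TRUE, nodes = 24) {
  stopifnot(inherits(spec, "mr_scenario_spec"))
  once <- function(nodes) {
    gh <- .gh_normal(nodes)
    g <- 0:2
    pg <- stats::dbinom(g, 2, spec$maf_instrument)
    grid <- expand.grid(g = g, c = gh$z, u = gh$z, e = gh$z,
                        KEEP.OUT.ATTRS = FALSE)
    w <- pg[grid$g + 1L] * gh$w[match(grid$c, gh$z)] *
      gh$w[match(grid$u, gh$z)] * gh$w[match(grid$e, gh$z)]
    x <- spec$beta_instrument_exposure * grid$g +
      spec$beta_c_exposure * grid$c + spec$beta_u_exposure * grid$u +
      spec$exposure_sd * grid$e
    eta <- log(spec$or_exposure_incidence) * x +
      log(spec$or_c_incidence) * grid$c + log(spec$or_u_incidence) * grid$u
    if (selected) {
      alpha <- stats::uniroot(
        function(a) sum(w * expit(a + eta)) - spec$target_prevalence,
        c(-30, 30), tol = 1e-12)$root
      w <- w * expit(alpha + eta)
    }
    w <- w / sum(w)
    prog <- spec$beta_exposure_progression * x +
      spec$beta_c_progression * grid$c + spec$beta_u_progression * grid$u
    mg <- sum(w * grid$g); mp <- sum(w * prog)
    (sum(w * grid$g * prog) - mg * mp) / (sum(w * grid$g^2) - mg^2)
  }
  coarse <- once(nodes); fine <- once(2L * nodes)
  if (abs(fine - coarse) > 1e-3)
    stop(sprintf(
      "quadrature grid too coarse: slope changed by %.2g on refinement; increase nodes (used %d)",
      abs(fine - coarse), nodes), call. = FALSE)
  fine
}
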