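# Shared fixtures: everything is generated in code at test time.

# A fast spec for structural tests: small cohort, cheap calibration.
tiny_spec <- function(..., n_individuals = 4000, seed = 42) {
  scenario_spec(n_individuals = n_individuals, seed = seed, ...)
}

quick_cal <- function(spec) calibrate_intercept(spec, calibration_size = 1e5)

quick_pop <- function(spec, replicate = 1L) {
  simulate_population(spec, replicate, intercept = quick_cal(spec))
}

# Mean case-only estimate of `target` over `n_rep` replicates; returns the
# stacked effect rows.
replicate_effects <- function(spec, target, n_rep, fn = case_only_effect,
                              ...) {
  intercept <- quick_cal(spec)
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    pop <- simulate_population(spec, r, intercept = intercept)
    fn(pop, target, ...)
  }))
}

# Monte-Carlo standard error of a mean of replicate estimates.
mc_se <- function(est) stats::sd(est) / sqrt(length(est))

# The acceptance suite shares one desk-scale reproduction run (200
# replicates of n = 50,000 per preset); memoized so the criteria reuse it.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_report <- function() {
  if (is.null(.acceptance_cache$report))
    .acceptance_cache$report <- run_table1(seed = 104729,
                                           n_replicates = 200)
  .acceptance_cache$report
}
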