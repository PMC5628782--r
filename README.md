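# collidersim

Collider bias (index event bias) in case-only studies of disease
progression — a simulation, estimation and mitigation toolkit in R.

## The problem

Progression GWAS and Mendelian randomization (MR) studies of progression
analyze only people who already have the disease. Disease incidence is a
**collider**: variants and other risk factors jointly cause it, so
conditioning on it (selecting cases) induces associations among all of its
causes. Concretely, in the DAG

```
   A ──────────────┐
   C ──┬───────► incidence   (cases selected here)
   U ──┤             
   C ──┴──► progression
   U ──────► progression
   B ──────► progression
```

* **A** (incidence only, per-allele OR 1.3, MAF 0.2, true progression
  effect 0) acquires a spurious case-only progression effect;
* **C** (measured; incidence OR 1.3/SD, progression effect 0.1/SD) has its
  case-only effect attenuated toward the null;
* **B** (progression only) is untouched — the bias needs an incidence
  effect;
* in MR, an instrument for an exposure that causes incidence is no longer
  independent of exposure–outcome confounders among cases (assumption 2
  fails).

The size of both distortions grows with the unmeasured confounding
**U**, indexed here by four presets: `low` (incidence OR 1.5, progression
effect 0.5), `moderate` (2, 0.8), `high` (2.5, 1), `strong` (3, 1.5).
Disease is logistic with the intercept calibrated to prevalence 0.2;
progression is normal, observed among cases.

## Worked example

```r
library(collidersim)

spec <- scenario_preset("strong", seed = 3)
pop  <- simulate_population(spec)          # n = 50,000, ~10,000 cases

case_only_effect(pop, "genotype_a")
#>        term estimate      se   ci_low  ci_high n_used degenerate
#>  genotype_a -0.04224 0.02495 -0.09115 0.006665  10200      FALSE

expected_case_only_slope(spec, "genotype_a")   # quadrature oracle
#> [1] -0.06602128

collider_diagnostics(pop)
#> Collider-bias checklist for variant 'genotype_a' (confounder 'c')
#>   [1] variant-incidence log-OR                       population +0.2351 (SE 0.0189) warn
#>   [2] variant-confounder slope                       population -0.0034 (SE 0.0079) ok
#>   [2] variant-confounder slope                       cases      +0.0045 (SE 0.0166) ok
#>   [3] case-only progression effect (unadjusted)      cases      -0.0422 (SE 0.0250)
#>   [3] case-only progression effect (adjusted)        cases      -0.0423 (SE 0.0250)
#>   [4] IPW progression effect (true probabilities)    cases      +0.0230 (SE 0.0284)
#>   [4] IPW progression effect (fitted weights)        cases      -0.0349 (SE 0.0263)
```

A variant with **zero** true progression effect shows a case-only effect
of −0.04 in this replicate (the long-run value under strong confounding
is −0.066, from the quadrature oracle). The checklist flags the incidence
association (item 1, log-OR ≈ log 1.3), shows adjustment for the measured
confounder barely helps here (the bias runs through unmeasured U), and
shows inverse-probability weighting with the true selection probabilities
recovering the null.

The full coverage study:

```r
report <- run_table1(seed = 1, n_replicates = 500)   # ~40 s on one CPU
print(report)
#> | Simulated scenario | low (OR = 1.5, beta = 0.5) | moderate (OR = 2, beta = 0.8) | high (OR = 2.5, beta = 1) | strong (OR = 3, beta = 1.5) |
#> |---|---|---|---|---|
#> | Apparent effect of A on progression (true 0) | -0.01 (0.01) | -0.02 (0.02) | -0.04 (0.02) | -0.07 (0.03) |
#> | Percentage of 95% CI including 0 | 90% | 70% | 51% | 29% |
#> | Apparent effect of C on progression (true 0.1) | 0.09 (0.01) | 0.08 (0.01) | 0.06 (0.01) | 0.04 (0.02) |
#> | Percentage of 95% CI including 0.1 | 82% | 40% | 10% | 1% |
```

Read it as: as unmeasured confounding strengthens, the null variant A
drifts to −0.07 and its CIs cover the true zero only 29% of the time,
while the real effect of C (0.1) is attenuated to 0.04 with 1% coverage.

The MR demonstration (`run_mr_demo(mr_scenario_spec(seed = 1))`) shows a
full-cohort Wald ratio centred on the true causal effect while the
case-only ratio is biased whenever the exposure causes incidence and
shares confounders with progression.

## Command line

```sh
Rscript inst/cli/collidersim.R simulate --scenario strong --n 50000 --seed 7 --out pop
Rscript inst/cli/collidersim.R table1   --n-replicates 200 --seed 1 --out table1
Rscript inst/cli/collidersim.R mitigate --scenario strong --seed 1 --out checklist
Rscript inst/cli/collidersim.R mr-demo  --true-effect 0 --seed 1 --out mr
```

(Use `system.file("cli", "collidersim.R", package = "collidersim")` after
installation.)

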