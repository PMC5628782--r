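---
title: "Collider bias in case-only studies of disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collider bias in case-only studies of disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collidersim)
```

## The problem

Genetic studies of disease *progression* (severity, recurrence, survival)
are by construction restricted to people who already have the disease.
Disease incidence is a collider: it is caused jointly by genetic variants
and by other risk factors. Conditioning on it — which is exactly what
selecting cases does — opens non-causal paths between everything upstream
of incidence. Two consequences matter for a case-only progression GWAS:

* a variant **A** that influences incidence *only* acquires a spurious
  association with progression, transmitted through its induced
  association with factors that affect both incidence and progression;
* a shared risk factor **C** that truly affects progression has its
  case-only effect attenuated, because selection induces compensating
  negative associations with the other incidence risk factors.

The same mechanism breaks Mendelian randomization (MR) of progression:
when the exposure causes disease onset, its genetic instrument is, among
cases, no longer independent of the confounders of the
exposure–progression relationship — a violation of the second MR
assumption.

`collidersim` makes both phenomena reproducible and testable at desk
scale: a calibrated synthetic-cohort generator, the case-only estimators
whose bias and coverage the selection distorts, an independent quadrature
oracle, the standard four-step mitigation checklist, and an MR
demonstration.

## The generative model

One replicate cohort of `n_individuals` contains, independently per
individual,

* `genotype_a` \(\sim \mathrm{Binomial}(2, 0.2)\): additive biallelic
  variant with per-allele incidence odds ratio 1.3 and **no** progression
  effect (the standard GWAS coding; the generator states allele frequency
  and per-allele odds ratios, so additive coding is the natural reading);
* `c`, `u` \(\sim N(0,1)\): a measured and an unmeasured risk factor for
  both incidence and progression; `c` has incidence OR 1.3 per SD and
  progression effect 0.1;
* disease \(\sim \mathrm{Bernoulli}\big(\mathrm{expit}(\alpha +
  \log(1.3)A + \log(1.3)C + \log(\mathrm{OR}_U)U)\big)\), with \(\alpha\)
  calibrated so the marginal prevalence is 0.2;
* progression \(= 0.1\,C + \beta_U U + \varepsilon\),
  \(\varepsilon \sim N(0, \sigma^2)\), generated for everyone but treated
  as observable only among cases.

Four presets index the degree of unmeasured confounding
\((\mathrm{OR}_U, \beta_U)\): `low` (1.5, 0.5), `moderate` (2, 0.8),
`high` (2.5, 1) and `strong` (3, 1.5). An optional variant **B**
(progression effect 0.1, no incidence effect) demonstrates the immunity
of progression-only variants to the selection. Several independent `u`
columns can be requested by passing vectors to `or_u_incidence` /
`beta_u_progression`; the default is a single one, which is the most
parsimonious reading of the design.

### Choices the model statement leaves open

**Incidence link.** Effects on incidence are stated as odds ratios, so
the incidence model is logistic. Its intercept has no closed form under
the binomial-plus-normal covariate mix, so `calibrate_intercept()` finds
it by root-finding on a fixed-seed Monte-Carlo draw (default \(10^6\)
individuals, prevalence error below 0.005, deterministic given the spec's
seed). The quadrature oracle recalibrates its own intercept by
deterministic root-finding on the Gauss–Hermite grid, so the two routes
stay independent.

**Progression residual SD (`residual_sd`).** The design fixes every
systematic coefficient but not the noise SD \(\sigma\). Point biases are
invariant to it; standard errors and hence CI coverage are not. We
calibrated it against the *standard errors* the design implies at roughly
10,000 cases: \(\sigma = 0.7\) is in the narrow band (about 0.65–0.70)
where all eight per-cell model SEs round to the reference values (0.01–
0.03 for A, 0.01–0.02 for C) at two decimals. We deliberately did not
tune it to coverage percentages — see *Known limitations*.

**Univariable by default.** The case-only fits for A and C are two
separate univariable regressions, matching the two separate rows of the
reference table; `joint = TRUE` fits them jointly. Quadrature shows the
two specifications differ by well under 0.002 in every cell, so nothing
downstream hinges on the choice.

**Wald intervals.** 95% CIs are `estimate ± 1.96·se` with the normal
quantile: at ~10,000 cases the t correction is far below everything else
in play.

**Seeds.** Every replicate's seed derives from
`derive_seed(master, replicate, stream)` — a linear-congruential mix
modulo \(2^{31}-1\) computed exactly in doubles — so any replicate can be
regenerated alone and identical configurations give byte-identical
outputs. Calibration uses its own stream; the four presets of a table run
use per-preset master seeds derived from the run seed.

**Degenerate replicates.** A replicate with fewer than 30 cases or no
genotype variation among cases is flagged, dropped from summaries, and
counted (`n_dropped`) — never silently imputed. At the default design
(10,000 expected cases) this never fires; it protects small custom
scenarios.

## The reproduction

```{r, eval = FALSE}
report <- run_table1(seed = 1, n_replicates = 500)
print(report)
```

Each cell pools 500 replicates of n = 50,000: the mean case-only
coefficient, the mean model SE, the empirical SD of the coefficients, and
the percentage of replicate 95% CIs containing the truth (0 for A, 0.1
for C). The run above takes about 40 seconds on one CPU; the test suite
uses 200-replicate runs and small cohorts, sizes we consider fully
adequate for the Monte-Carlo tolerances they are checked at.

With seed 1 and 500 replicates the mean coefficients are
A: −0.009 / −0.025 / −0.039 / −0.066 and C: 0.091 / 0.076 / 0.062 /
0.035 across low → strong, with coverages A: 90 / 70 / 51 / 29 and
C: 82 / 40 / 10 / 1 percent. The bias of A grows, and the attenuation of
C deepens, monotonically with the unmeasured confounding, while the
full-cohort fits stay unbiased — selection on the collider, not case
analysis per se, creates the bias.

## The quadrature oracle

`expected_case_only_slope()` computes what the case-only slope converges
to without simulating: genotype is enumerated, C and U are integrated on
a Gauss–Hermite grid (48 nodes per dimension by default, checked against
a doubled grid and refused if the refinement moves the slope by more than
\(10^{-3}\)), each cell is weighted by its probability times the
calibrated case-selection probability, and the weighted least-squares
projection of the conditional progression mean is solved in closed form.
The tests require simulation means to sit within 3 Monte-Carlo SEs of the
oracle in all eight preset cells, and the oracle also supplies signs and
magnitudes for the mitigation and MR checks (e.g. the induced
case-only slope of C on A under strong confounding, −0.0103).

## Mitigation checklist

`collider_diagnostics()` runs the four standard steps on a cohort:

1. **Variant–incidence check** — logistic fit of disease on the variant;
   a real incidence effect flags collider-bias potential for any
   case-only progression result.
2. **Variant–confounder check** — the confounder regressed on the variant
   among cases *and* in the population; an association present only among
   cases is the induced one. No universal "concerning" effect size
   exists, so the report emits estimates with `warn` flags at |z| > 1.96
   rather than verdicts.
3. **Adjustment** — `adjusted_case_only_effect()` blocks the induced path
   through measured C. Quadrature confirms it restores the null exactly
   when C is the only shared factor and helps only marginally under the
   presets, where U dominates (strong preset: −0.0660 unadjusted vs
   −0.0657 adjusted) — unmeasured confounding remains the problem.
4. **Inverse-probability-of-selection weighting** —
   `ipw_case_only_effect()` reweights cases by 1/P(disease | covariates),
   rescaled to mean 1 (stabilizes SEs, leaves the point estimate alone).
   With the generative probabilities (which know U) it recovers the truth
   for A, B and C under every preset; with weights fitted on measured
   covariates only, bias shrinks by the share the measured factors carry.
   Weight ratios beyond `max_weight_ratio` warn, with optional
   truncation; the default warns and does not truncate. Published
   closed-form bias corrections are outside this package's scope.

## MR of progression

`simulate_mr_population()` implements the instrumented-exposure DAG:
variant Z → exposure X → disease, confounders on X and on progression.
`wald_ratio()` computes the single-instrument ratio with a delta-method
SE and refuses first stages with |beta|/se ≤ 3. The reference design
gives no numbers for this DAG, so the defaults are *illustrative*, chosen
so the phenomenon is unambiguous at a few dozen replicates: MAF 0.3,
Z → X effect 0.3 per allele, X → incidence OR 2.5 per unit, confounder
effects 0.3/0.1 (measured) and 0.8/1.0 (unmeasured) on exposure/
progression, no direct confounder → incidence paths. Under a *null*
causal effect, the expected case-only instrument–progression slope is
−0.032 (quadrature), a case-only Wald ratio near −0.11; the full-cohort
ratio stays centred on the truth across effects {−0.3, 0, 0.3}. A subtle
point the tests encode: even with no exposure–outcome confounders at all,
case selection attenuates the case-only first stage and reduced form by
the same factor (through the exposure's own noise), so the case-only
ratio remains consistent — confounders of exposure and progression are
what make it inconsistent.

## Known limitations

* **Coverage is not exactly reproducible from the stated design.** The
  printed per-cell SEs of the reference table are not jointly consistent
  with any single progression noise SD under this DAG (the A-strong
  coverage of 35% implies \(\sigma \approx 1\); the C-low coverage of 72%
  implies \(\sigma \approx 0.4\)). With \(\sigma = 0.7\), calibrated to
  the printed SEs, our coverages reproduce the qualitative collapse
  (90 → 29 for A, 82 → 1 for C) and most cells quantitatively, but the
  moderate/high A cells run 8–15 points low and the low C cell ~10 points
  high. We report this as a limitation rather than re-tuning the
  generator: the point estimates, which are insensitive to \(\sigma\),
  reproduce everywhere.
* The cohorts are deliberately minimal: one biallelic variant per role,
  no linkage disequilibrium, no polygenicity, independent confounders,
  a continuous progression measure with no censoring or
  measurement error. Passing tests show the selection mechanism and its
  mitigation behave as the theory predicts in this clean setting — not
  that real progression GWAS, with survival outcomes, disease-stage
  confounding and correlated markers, are reduced to it.
* IPW inference uses model-based SEs by default; HC0 sandwich SEs are
  available via `robust = TRUE`. At ~10,000 cases with mean-1 weights the
  two differ little, and the reference design says nothing about
  inference for corrected estimates.
* The MR module is a single-instrument demonstration; polygenic scores,
  two-sample designs and pleiotropy-robust estimators are out of scope.
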