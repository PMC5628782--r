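Package: collidersim
Title: Collider Bias in Case-Only Studies of Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for index event (collider) bias
    in genetic studies of disease progression. Generates synthetic cohorts in
    which genetic variants and measured and unmeasured confounders act on
    disease incidence through a calibrated logistic model and on a continuous
    progression outcome among cases, fits the case-only regressions whose
    bias and confidence-interval coverage the selection mechanism distorts,
    provides an independent Gauss-Hermite quadrature oracle for the expected
    case-only slopes, implements the standard mitigation checklist (variant
    versus incidence, variant versus confounder diagnostics, confounder
    adjustment, inverse-probability-of-selection weighting), and demonstrates
    how case selection violates the second Mendelian randomization assumption
    for instruments of exposures that cause disease onset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    sandwich
Config/testthat/edition: 3
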