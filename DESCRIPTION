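Package: akisem
Title: Latent-Variable Modelling of Cardiac Surgery-Associated Acute Kidney
    Injury in Infants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end latent-variable analysis pipeline for perioperative
    acute kidney injury (AKI) after infant cardiopulmonary bypass surgery:
    per-patient derived metrics from clinical time series (trapezoidal and
    threshold-deficit areas under the curve, creatinine variation, oliguria,
    vasoactive-inotropic score, AKIN staging), exploratory factor analysis
    with varimax rotation and iterative variable refinement, a maximum
    likelihood structural equation modelling engine in RAM parameterisation
    with fit indices and Lagrange-multiplier modification indices, Wright
    path tracing for compound-effect decomposition, and nonparametric
    case-resampling bootstrap confidence intervals.  Includes a synthetic
    cohort generator that emulates the statistical structure of a published
    four-construct model (bypass exposure, low cardiac output, AKI, outcome)
    for parameter-recovery and structure-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
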