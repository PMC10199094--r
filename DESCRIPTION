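Package: retinocog
Title: Retinal Layer Thickness as a Longitudinal Diagnostic Test for Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning longitudinal cognitive scores (novel object
    recognition discrimination indices) and retinal layer thicknesses measured
    by optical coherence tomography into a binary diagnostic test for cognitive
    impairment. Implements the rolling monthly-change transform, eye averaging,
    simple and multiple linear regression with collinearity diagnostics
    (variance inflation factors, ANOVA partition, parameter correlation), a
    four-test normality battery with parametric/non-parametric dispatch, DSM-V
    style threshold derivation (mean minus k standard deviations of the
    monthly change in discrimination index, interpolated onto a retinal-layer
    regression line), 2x2 contingency classification under a test-of-health
    polarity, Fisher's exact test by hypergeometric enumeration, and the full
    basic and evaluative diagnostic metric battery (sensitivity, specificity,
    predictive values, likelihood and odds ratios, Youden's J, NND, NNM, PSI).
    Ships a synthetic-cohort generator with a known coupling between monthly
    change in inner nuclear layer thickness and monthly change in
    discrimination index, plus a deterministic reference cohort for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
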