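Package: polydev
Title: Classifying Individuals Who Deviate from Their Polygenic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies individuals whose quantitative phenotype is improbably
    far from the value predicted by their polygenic score under the additive
    polygenic model. Implements four classification methods calibrated by
    simulation: Mahalanobis distances against a simulated-null covariance with
    chi-squared (2 df) p-values, standardized regression residuals, empirical
    p-values from rank-matched simulated cohorts, and non-parametric Tukey
    fences within score centiles. Includes an additive polygenic-model
    simulator with planted deviators for method evaluation, downstream
    enrichment statistics (odds ratios and covariate-adjusted regressions
    against the aligned group), and an end-to-end pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
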