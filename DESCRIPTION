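Package: trionurture
Title: Trio Mendelian Randomization of Parental BMI Effects with a
    Synthetic Cohort Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effects of parental body mass index on offspring
    adiposity and diet using within-family (trio) Mendelian randomization:
    polygenic-index construction from GWAS summary statistics, weighted
    two-stage least squares with parental polygenic indices as instruments
    conditional on the offspring index, phenotypic multivariable regression,
    a three-index direct/indirect genetic-effect decomposition, Rao-Wu
    survey bootstrap for coefficient contrasts, and inverse-probability
    non-response weighting. Ships a synthetic trio-cohort simulator with
    assortative mating, genetic nurture, parental self-report error and
    BMI-dependent attrition, so every estimator is validated by parameter
    recovery without restricted cohort data. Includes LMS growth-reference
    z-scoring and a multiple correspondence analysis diet factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
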