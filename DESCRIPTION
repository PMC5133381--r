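Package: mrsens
Title: Sensitivity Analyses for Two-Sample Mendelian Randomization with
    Summarized Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators and diagnostics for Mendelian randomization with
    multiple genetic variants from two-sample summarized data
    (per-variant beta-coefficients and standard errors). Provides
    per-variant ratio (Wald) estimates, fixed-effect and multiplicative
    random-effects inverse-variance weighted estimators, Egger regression
    with the intercept test for directional pleiotropy, simple and
    weighted median estimators with parametric-bootstrap confidence
    intervals, multivariable inverse-variance weighting, Cochran's Q
    heterogeneity test with per-variant contributions and outlier
    pruning, leave-one-out / leave-k-out / random-subset robustness
    analyses, scatter, funnel and ordered-subset diagnostic plots, and a
    simulation engine with known truth for studying the estimators'
    operating characteristics under configurable pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
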