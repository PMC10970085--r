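Package: stressindex
Title: Chronic Stress Indicator and Allostatic Load Indices from Complex Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the ten-component Chronic Stress Indicator (CSI) and
    Allostatic Load (AL) composite risk indices from participant-level survey
    extracts, and compares them with fully design-based statistics for
    stratified multi-stage samples: survey-weighted means and proportions with
    Taylor-linearized standard errors, the Rao-Scott second-order corrected
    chi-square, a design-based Wilcoxon rank-sum test, survey-weighted
    logistic regression with linearized sandwich variances, Cramer's V and
    Pearson association matrices, variance-inflation factors, and
    maximum-likelihood exploratory factor analysis of the index components.
    Includes a synthetic cohort generator emulating stratified two-stage
    sampling with unequal weights so the whole pipeline is testable without
    restricted survey data, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
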