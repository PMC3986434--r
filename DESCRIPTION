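Package: ancovasim
Title: Bias, Precision and Power of ANOVA, Change-Score Analysis and
    ANCOVA Under Baseline Imbalance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo machinery for two-arm randomized trials with a
    continuous outcome measured at baseline and follow-up. Simulates
    trials under a bivariate-normal generative model with a controlled
    baseline-outcome correlation, standardized treatment effect and
    standardized baseline imbalance; fits the three standard analyses
    (unadjusted comparison of outcome means, change-score analysis, and
    analysis of covariance) by closed-form ordinary least squares; and
    aggregates bias, design effects (ratios of mean standard errors) and
    conditional statistical power over a factorial grid of scenarios.
    Closed-form algebraic predictions for bias, relative precision and
    approximate power are provided as independent checks, together with
    noncentral-t sample-size computation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
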