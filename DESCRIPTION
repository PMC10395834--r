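Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of Gut-Microbial
    Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for nominating causal
    gut-microbial biomarkers of disease from GWAS summary statistics.
    Implements instrument selection and harmonization (palindrome
    handling, LD clumping, weak-instrument filtering), univariable
    two-sample Mendelian randomization (Wald ratio, inverse-variance
    weighted with multiplicative random effects, MR-Egger) with
    Cochran's Q, Steiger directionality, MR-PRESSO outlier detection,
    and approximate-Bayes-factor colocalization; Bayesian model
    averaging over multivariable MR models (marginal inclusion
    probabilities and model-averaged causal effects with influence
    diagnostics); two-step mediation analysis with delta-method
    standard errors; and a cross-method consensus table.  A seeded
    synthetic GWAS summary-statistics generator with known ground
    truth supports calibration and recovery experiments for every
    stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
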