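Package: socialdisc
Title: Social Discounting Analysis for High-Psychopathy Community Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing social discounting tasks in which
    participants make repeated binary choices between keeping money and
    splitting it with people at increasing social distance. Converts raw
    dichotomous choices into per-distance indifference points and amounts
    willing to forgo, fits hyperbolic, exponential and linear discounting
    models per participant and pooled (with AIC model selection and Akaike
    weights), computes log discount rates (logk) and model-agnostic
    trapezoidal area under the curve (AUC), and carries the derived metrics
    through group and continuous inference: Welch t-tests with Cohen's d,
    chi-squared tests, multiple regression with fully standardized
    coefficients, moderation, logistic odds ratios, and Bonferroni
    correction. Includes a simulation-based causal mediation engine
    (quasi-Bayesian and bootstrap ACME/ADE/total/proportion mediated),
    reliability statistics (Cronbach's alpha, one-way random-effects ICC),
    and robustness procedures (k-fold cross-validation, greedy caliper
    propensity-score matching). A synthetic-cohort generator reproduces the
    statistical structure such studies assume, so the whole pipeline is
    testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
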