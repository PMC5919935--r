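Package: moodchoice
Title: Mood Dynamics and Risky-Choice Modelling with Bayesian Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling momentary mood as a leaky integration of
    feedback events and for modelling accept/decline decisions about risky
    motor challenges under expected utility. Provides the full model families
    (18 mood models, 132 choice models, 16 neural-proxy modulation variants),
    approximate-Bayesian model inversion via the Laplace approximation,
    group-level random-effects Bayesian model selection with exceedance
    probabilities and family comparison, a synthetic-cohort generator
    emulating a quiz-plus-choice task design with biased feedback episodes,
    and trial-level regression analyses linking simulated region-of-interest
    baseline signals to choice parameters through a neural proxy for mood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
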