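Package: dustddm
Title: Drift-Diffusion Modelling of Perceptual Decisions Under Social Norms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of a two-alternative
    motion-discrimination task in which observers see the choices of other
    players (social information) alongside trial-level norm prompts that ask
    them to decide with or against those players.  Provides a Wiener
    first-passage-time likelihood engine (small- and large-time series
    expansions with closed-form drift-variability mixing), an
    exact-in-distribution diffusion simulator, six nested drift-diffusion
    model parametrizations in which social cues act on the starting point
    and/or the drift rate, differential-evolution MCMC posterior sampling,
    WAIC-based model comparison and Bayesian model averaging of
    condition-level starting-point biases and drift deltas, a seeded
    synthetic-cohort generator emulating the task design, model-free
    behavioural summaries (accuracy, conformity, payoff scoring, paired
    t-test power), and parameter-recovery and posterior-predictive
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
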