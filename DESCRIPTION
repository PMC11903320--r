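Package: pulsedyn
Title: Pulse-Based Analysis of Context-Dependent Evidence Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for context-dependent
    accumulation of pulsed sensory evidence. Provides a generator for a
    two-context (location versus frequency) auditory pulse task with
    Poisson-timed, labelled pulses; psychometric and feature-selection
    fits; time-binned behavioural kernels estimated by ridge-penalised
    logistic regression; a vanilla tanh recurrent network model with
    backpropagation-through-time training; fixed-point location and
    linearisation of network dynamics around line attractors; the
    decomposition of context-dependent evidence selection into selection
    vector modulation, direct input modulation and indirect input
    modulation, with barycentric-coordinate visualisation; closed-form
    engineering of input weights to place a network at any target mixture
    of the three mechanisms; pulse-based kernel regression of unit
    activity with choice-axis estimation; and the linking analysis that
    relates neural and behavioural kernel slope indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
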