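Package: mmnet
Title: Simulated Dynamic Causal Modelling of Auditory Mismatch Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of auditory change detection in a
    six-node cortical network. Generates multi-feature oddball tone
    sequences (Optimum-1 design), simulates per-condition source activity
    from a delayed neural-mass network model with condition-specific
    modulatory gains, preprocesses trial epochs (filtering, baseline
    correction, EOG-threshold artifact rejection, robust averaging),
    computes M100 and mismatch-response waveform metrics, inverts a space
    of fifteen competing connectivity models by variational Laplace to
    obtain free-energy bounds on model evidence, and performs hierarchical
    random-effects Bayesian model selection at the family and model level
    with exceedance probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    signal,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
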