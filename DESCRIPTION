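Package: popstate
Title: Population Coupling and ON/OFF Cortical State Analysis for Laminar Spike Recordings
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-neuron population coupling (the
    soloist-chorister continuum) and its relation to ON/OFF cortical state
    dynamics and spatial attention in laminar multielectrode recordings from
    visual cortex. Provides a columnar session data model with plain-text
    readers and writers, a synthetic-session generator with a latent two-state
    Markov process and per-channel Poisson firing, Gaussian-kernel population
    rate construction and stability and inclusion filters, zero-lag
    cross-correlation population coupling with Fisher z-transform, a
    multichannel Poisson hidden Markov model fitted by expectation
    maximisation with random restarts and decoded by the Viterbi algorithm,
    fourfold leave-one-channel-out cross-validated selection of the number of
    latent phases, per-unit ON/OFF firing-rate ratios, attention modulation
    indices, spike-count noise correlations and rate-matching controls, and
    laminar utilities (finite-difference current source density,
    signal-to-noise ratio, parametric response-latency fits, layer-compartment
    assignment, receptive-field z-maps).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
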