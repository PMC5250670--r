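Package: snncorr
Title: Degree Correlations, Stability and Stimulus Detection in Spiking
    Neural Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how correlations between the in- and
    out-degree of individual neurons shape the dynamics of recurrent
    spiking neural networks. Generates directed excitatory networks with
    prescribed joint degree distributions (anti-correlated, positively
    correlated, uncorrelated or mixed) via a truncated rotated bivariate
    Gaussian and the configuration method with collision repair; simulates
    Izhikevich-type networks of pyramidal, PV and Sst cells with
    conductance-based synapses, white-noise and Poisson background input
    and exact state snapshot/restore; detects network bursts from Gaussian
    spike-density traces; quantifies stimulus detectability with a paired
    state-reset ROC protocol; and implements additive and weight-dependent
    spike-timing dependent plasticity with global homeostatic scaling and
    synaptic pruning, together with graph-theoretical summaries (mean
    shortest path, k-core decomposition, degree-correlation statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    igraph,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
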