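Package: spikesampler
Title: Learning and Sampling Prior Distributions in Clustered Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-network spiking model that learns a discrete prior
    distribution by inverse transform sampling. A clustered network of adaptive
    exponential integrate-and-fire neurons switches randomly between metastable
    cluster states (a "uniform sampler"); plastic Hebbian weights with soft
    presynaptic normalization map those states onto an eight-cluster sensory
    network so that spontaneous activity samples from the stored distribution.
    Includes training and sampling protocols, decision-making read-outs
    (leaky integration of indicator functions, psychometric curves, history
    biases), a short-term-plasticity read-out that recodes probability as an
    instantaneous novelty signal, spike-train decoding and KL-divergence
    analyses, and a discrete cluster-level reference model used for
    property-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr,
    optparse
Config/testthat/edition: 3
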