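Package: synrecon
Title: Stochastic Simulation of Synaptic Reconsolidation with a Shared Pool of
    Stabilizing Entities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale simulator of synaptic reconsolidation in hippocampal
    slice paradigms. Consolidated synapses are maintained by a finite, shared
    pool of stabilizing entities with a protein-synthesis-inhibition (PSI)
    immune reservoir, layered on top of two consolidation models: a
    write-protected model with coupled bistable weight, tag and scaffold
    variables driven by triplet spike-timing-dependent plasticity in a leaky
    integrate-and-fire neuron, and a seven-state Markov model of synaptic
    strength. Includes a reduced two-dimensional mean-field model of the
    bound-synapse and reservoir dynamics used to map the boundary conditions
    of reconsolidation, stimulation-protocol generators (low- and
    high-frequency stimulation, PSI and dopamine windows), experiment runners
    with repeat averaging, and ggplot2 visualisation of results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
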