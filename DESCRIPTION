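Package: spikeamp
Title: Linear-Complexity Spiking Neural Network Classification of
    Amperometric Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of amperometric current waveforms (vesicle-fusion
    transients recorded during exocytosis) with a spiking neural network of
    linear computational complexity.  The network uses Izhikevich tonic-spiking
    and inhibition-induced-spiking neurons in a single hidden layer, capacitive
    synapses with zero weight dispersion into one output neuron, an analytic
    one-pass weight-mapping rule in place of iterative training, and a
    two-latency spike-timing response code.  Includes a synthetic generator of
    labelled fusion and non-fusion waveforms, end-to-end evaluation tools, and
    a Monte Carlo analysis of robustness to fabrication-style weight mismatch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
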