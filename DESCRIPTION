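Package: dendrogate
Title: Inhibitory Gating of Dendritic Coincidence Signals in Pyramidal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based multi-compartment simulation of a simplified
    pyramidal neuron and the inhibitory gating of its dendritic coincidence
    signals. The package builds a branched cable model with Hodgkin-Huxley
    style sodium, potassium and calcium channels, integrates it with an
    implicit Hines solver, and provides the stimulation protocols, spike and
    calcium-spike measures, an additive spike-timing-dependent plasticity
    (STDP) pairing protocol, and a two-cell feedforward-inhibition circuit
    needed to study how shunting GABA-A inhibition switches backpropagating
    action potentials, dendritic calcium spikes, and hence Hebbian plasticity
    on and off in an all-or-none manner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
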