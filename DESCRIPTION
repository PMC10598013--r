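Package: fracml
Title: Discrete Fractional-Order Morris-Lecar Neuron Models and Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for discrete fractional-order
    (Caputo delta-difference) Morris-Lecar neuron models.  Implements the
    explicit memory-convolution solver for commensurate and incommensurate
    fractional orders, the two-variable conductance-based neuron and its
    three-variable slow-fast extension, equilibrium location and
    Matignon-type stability analysis with Hopf threshold orders,
    Erdos-Renyi coupled populations with mixed fractional orders, a
    reduced-order cluster model, and regime classification (quiescent,
    tonic spiking, bursting, mixed-mode oscillations) with bifurcation
    sweeps and synchronization metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
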