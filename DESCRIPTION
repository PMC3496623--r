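Package: gifnet
Title: Spike-Train Statistics of Stochastic Conductance-Based
    Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and spike-train statistics toolkit for stochastic
    conductance-based (generalized) integrate-and-fire networks with
    alpha-kernel synapses.  Computes exact conditional spike
    probabilities, the Gibbs potential of raster plots and its
    finite-memory truncations and monomial expansion, together with
    closed-form bounds on conductances, membrane potentials, noise
    variance and firing probabilities, and tools for measuring the
    exponential decay of memory (m-variation) against analytic
    envelopes.  Rasters can be generated two independent ways: exact
    sequential sampling from the conditional spike law, or
    Euler-Maruyama integration of the underlying stochastic membrane
    equation with threshold and random reset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
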