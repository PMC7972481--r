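Package: ttlnet
Title: Sequence Learning in Modular Spiking Networks with Two-Trace
    Eligibility Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates stimulus-selective cortical columns of Timer/Messenger
    microcircuits that learn both the duration and the order of stimulus
    sequences through a reinforcement rule based on competing LTP and LTD
    eligibility traces, gated by a global novelty neuromodulator. Provides a
    conductance-based leaky integrate-and-fire backend and an equivalent
    rate-based backend, a three-stage extension (reservoir plus sparse
    pattern network) for non-Markovian sequences, analytic fixed-point
    solvers for the learning rule, end-to-end training and recall protocols,
    and measurement operators for recalled durations, order, convergence and
    interspike-interval statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
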