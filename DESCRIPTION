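Package: pcsnet
Title: Predictive-Coding Spiking Networks with Heterogeneous Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of spiking neurons that track a
    one-dimensional signal by greedy error reduction: each spike is fired only
    if it lowers the mean-squared error of a delayed linear reconstruction of
    the input. Provides Gamma-function filter banks (type-1 "integrator",
    type-2 "resonator", off-cells, and heterogeneous populations), synthetic
    stimulus and correlated-noise generators, the delayed greedy spike-rule
    simulator with linear spike cost and adaptive thresholds, performance
    metrics (spike-train coincidence factor, normalized mean-squared error,
    network activity, coding efficiency), and characterization protocols
    (f-I curves, phase-response curves, spike-triggered averages,
    signal/noise cross-correlograms, spike-triggered population activity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
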