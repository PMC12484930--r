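Package: dsrpp
Title: Doubly Stochastic Renewal Point Processes for Partitioning Spiking Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and estimation tools for doubly stochastic renewal
    (DSR) point processes, a generative model of neural spike trains in which
    a stochastic instantaneous firing rate drives a renewal process with
    gamma-distributed interspike intervals in operational time. Partitions
    spike-count variance into firing-rate fluctuations and spiking
    irregularity (phi, the squared coefficient of variation of the
    operational-time interval distribution), estimates phi with a
    moment-based two-bin quadratic method alongside deterministic
    time-rescaling and minimum-ratio reference estimators, validates the
    framework on (synthetic) intracellular voltage traces via a fitted
    voltage-to-rate map, and simulates a spatially ordered balanced network
    of exponential integrate-and-fire neurons in which irregularity emerges
    from circuit dynamics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
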