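Package: stngpe
Title: Spatially Embedded STN-GPe Spiking-Network Model with Coordinated Reset Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scale-configurable simulator of the subthalamic nucleus (STN) -
    globus pallidus externus (GPe) loop built from single-compartment
    conductance-based (Terman-Rubin) neurons placed in ellipsoidal nuclei with
    distance-dependent connectivity. Excitatory STN-STN synapses are governed
    by an additive asymmetric spike-timing-dependent plasticity rule with hard
    bounds, which makes the network bistable between a strongly synchronized
    ("parkinsonian") and a desynchronized ("healthy") attractor. The package
    generates charge-balanced biphasic pulse trains delivered through a
    multi-contact depth electrode under a randomized coordinated-reset (CR)
    schedule, and quantifies synchrony via Kuramoto order parameters on
    linearly interpolated spike phases, a voxelized local order parameter, and
    interspike-interval statistics. Experiment runners reproduce spontaneous
    regimes, weight bistability, CR amplitude scans and electrode-displacement
    scans at reduced scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    deSolve,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
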