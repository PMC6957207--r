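Package: camkiisim
Title: Rule-Based Stochastic Simulation of the CaMKII Holoenzyme
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Well-mixed stochastic simulation of the twelve-subunit
    Ca2+/calmodulin-dependent protein kinase II (CaMKII) holoenzyme as a
    rule-based multi-state model. Each subunit carries five flags (hub
    docking, conformational activation, two-step calmodulin binding,
    Thr-286 phosphorylation/phosphatase occupancy, Thr-306
    phosphorylation); transitions are guarded rules with published rate
    constants. Three interchangeable engines advance the system (exact
    SSA, a quasi-steady-state-accelerated SSA that marginalises the fast
    conformational flicker, and an MCell-like fixed-timestep Bernoulli
    scheme), driven by square-wave Ca2+/calmodulin forcing, pulse trains,
    boluses and timed kinase/phosphatase inhibitor events. Includes model
    variants (exclusive vs non-exclusive calmodulin/phosphatase binding,
    autophosphorylation degrees of freedom, a 9-state-1-step calmodulin
    model with Ca2+ lobe kinetics and CaM trapping), ensemble observables
    (flag-count time courses, decay constants, frequency-response fits,
    consecutive-pT286 run statistics), and an exact chemical-master-
    equation oracle for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
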