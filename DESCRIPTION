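Package: rpsim
Title: Multi-Agent Simulation of RNA Replicase-Parasite Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Off-lattice, individual-based simulator of a prebiotic RNA-world
    ecosystem of replicases and parasites. Brownian molecules on a 2D torus
    carry two mutable attributes, an affinity towards replicases and a
    folded-state probability, form transient catalyst-template complexes, and
    replicate with mutation under exponential waiting-time kinetics. The
    package provides the discrete-step scheduler (complex lifecycle, decay,
    crowding removal), the calculus that converts cellular-automaton move
    probabilities into off-lattice diffusion coefficients by variance
    matching, presets for published experiment scenarios, per-step population
    observables, frame rendering and a small command-line interface. The
    compute core is written in C++ with a cell-list neighborhood grid and a
    seeded private random-number stream so that a (configuration, seed) pair
    fully determines a run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
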