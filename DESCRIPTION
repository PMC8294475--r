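Package: ljtyping
Title: Data-Driven Lennard-Jones Atom Typing and Parameter Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for asking how many Lennard-Jones (LJ) atom types a
    force field actually needs. Provides SMIRKS-rule typing models with
    last-match-wins priority over CHON organic molecules, Lorentz-Berthelot
    combining rules and the physical-to-mathematical parameter transform, a
    regularized property-matching objective (densities, heats of
    vaporization, dielectric constants), damped Gauss-Newton optimization
    with triplicate multi-start and a greedy type-splitting search,
    refinement-lattice consistency diagnostics for local-minimum trapping,
    scaled Euclidean distances between typing models in parameter space,
    a desk-scale rigid-molecule NPT Metropolis Monte Carlo simulator for
    toy liquids, and a synthetic compound library plus property oracle so
    the whole pipeline runs without molecular dynamics or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
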