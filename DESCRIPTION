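Package: hoprelay
Title: Stochastic Hopping-and-Relay Simulation and Trajectory Analysis of
    ParABS Plasmid Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based stochastic model of intracellular cargo
    positioning by the ParABS partitioning system.  ParA-ATP dimers bind a
    two-dimensional rectangular nucleoid, fluctuate elastically about home
    positions, hop diffusively between DNA strands, and tether a
    ParB-coated plasmid whose motion follows the resultant elastic force.
    The package provides a fast compiled simulator together with the
    quantitative trajectory-analysis toolkit used to characterise such
    systems: over-damped-spring (Ornstein-Uhlenbeck) velocity-profile
    estimators of the relaxation time and diffusion coefficient,
    dimensionless parameters (lambda, epsilon, theta) organising the phase
    space, phase-regime descriptors (phi, psi, chi) with grid scans, a
    sliding-window oscillation classifier, synthetic-trajectory generators
    with known ground truth, and readers/writers for plasmid tracking
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
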