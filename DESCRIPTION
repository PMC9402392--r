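Package: twostateSBM
Title: Dual-Basin Structure-Based Models of Two-State Protein Conformational Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained (C-alpha) dual-basin structure-based
    ("Go-like") models of proteins that interconvert between two crystallographic
    conformations, such as the open and closed states of periplasmic binding
    proteins. Detects native residue-residue contacts in each state, classifies
    them as common or state-specific with a distance-ratio rule, assembles a
    potential in which common contacts carry dual-Gaussian wells (one minimum per
    state) and state-specific contacts carry 10-12 wells, and propagates the model
    with reduced-unit Langevin (BAOAB leapfrog) dynamics in the NVT ensemble.
    Includes reaction-coordinate and free-energy-profile analysis, hysteretic
    two-state assignment and transition counting, salt-bridge monitoring for
    all-atom trajectories, a closed-state contact-strength tuning protocol, a
    synthetic two-state protein generator so the whole pipeline is testable
    without downloads, and a configuration-driven pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
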