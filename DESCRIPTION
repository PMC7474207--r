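Package: gopull
Title: Coarse-Grained Go-Model Pulling Simulations and Unfolding Free-Energy
    Estimation for Helix-Bundle Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure-based (Go-type) coarse-grained simulation of mechanical
    protein unfolding at C-alpha resolution, with three routes to the
    unfolding free-energy profile along the end-to-end reaction coordinate:
    constant-velocity steered pulling with accumulated work, boxed dynamics
    (BXD) with box-to-box rate constants, and umbrella sampling unbiased by
    the weighted histogram analysis method (WHAM). Includes a PDB C-alpha
    reader, native contact maps by the van der Waals overlap criterion,
    an overdamped Langevin engine, synthetic helix-bundle generators for
    download-free testing, and trajectory analyses (helicity, inter-helix
    contact fractions, unfolding intermediates such as three-helix states).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
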