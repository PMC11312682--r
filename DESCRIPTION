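Package: mesopair
Title: Force-Field Pair Interaction Energies, Coordination Numbers and
    DPD Repulsion Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated calculation of force-field-based intermolecular pair
    interaction energies for small organic molecules: exhaustive rigid-body
    dimer configuration sampling on Fibonacci sphere lattices with
    multi-resolution distance refinement, Boltzmann-weighted interaction
    curves, a minimal periodic molecular dynamics engine with an Andersen
    thermostat for coordination-number estimation (brute-force and cell-index
    neighbor counting), and the derivation of differential pair interaction
    energies, Flory-Huggins parameters and Dissipative Particle Dynamics
    (DPD) repulsion parameter sets. Supports a generic Lennard-Jones plus
    point-charge energy model with bundled fixture molecules and an MMFF94
    backend for parameter assignment and all-atom dimer optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
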