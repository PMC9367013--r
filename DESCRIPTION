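Package: flmoeda
Title: Fragment Localized Molecular Orbitals and Interaction Energy Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Top-down variational localization of Hartree-Fock occupied
    orbitals into user-defined molecular fragments (fragment localized
    molecular orbitals, FLMOs), and a fragment-pair interaction-energy
    decomposition into electrostatic, exchange and electronic-preparation
    components with optional counterpoise correction and pluggable pairwise
    dispersion. Includes a compiled Gaussian AO integral engine (overlap,
    kinetic, nuclear attraction, two-electron repulsion), restricted and
    unrestricted Hartree-Fock drivers, pivoted-Cholesky fragment guesses,
    XYZ/PDB readers, Gaussian cube export, programmatic small-molecule
    fixtures and an end-to-end pipeline with JSON/CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
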