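Package: vetflow
Title: Vibrational Energy Transport Networks in Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-derived master-equation modelling of vibrational energy
    transfer (VET) in peptides. Builds inter-residue rate networks from PDB
    structures (backbone, interstrand hydrogen-bond and heater-contact
    channels plus heater source and solvent sink), integrates the linear
    master equation exactly, decomposes sensor-arriving energy into pathway
    classes both exactly (flag-augmented state space) and by Monte Carlo
    jump-chain sampling, calibrates transport coefficients and a global
    quantum-correction factor against observed residue-energy traces and
    experimental peak times, and forward-models transient infrared difference
    spectra of a red-shifting azide reporter band. Ships a synthetic-data
    generator (idealized beta-hairpin structures and noisy MD-like energy
    ensembles) so the full analysis runs without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    bio3d,
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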