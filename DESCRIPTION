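Package: fretburst
Title: Burst Analysis, Corrections and Dynamics for Single-Molecule FRET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of diffusion-based single-molecule FRET measurements
    with alternating excitation (usALEX/PIE): photon-stream data model and
    I/O, background estimation and all-photon burst search, determination
    and application of the four correction factors (alpha, beta, gamma,
    delta) for accurate FRET efficiencies and stoichiometries, Gaussian
    population fits with cross-laboratory consensus statistics, Forster
    conversion of efficiencies to interdye distances with propagated
    uncertainties, detection and quantification of conformational dynamics
    (burst variance analysis, E versus donor-lifetime analysis with static
    and dynamic FRET lines, dynamic photon distribution analysis,
    species-filtered fluorescence correlation spectroscopy, maximum-entropy
    inversion of donor decays), accessible-volume and accessible-contact-
    volume dye models on PDB structures, and time-resolved anisotropy
    analysis with kappa-squared based distance-uncertainty filtering.
    Includes a photon-level simulator of freely diffusing labelled
    molecules that provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    mclust,
    bio3d,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
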