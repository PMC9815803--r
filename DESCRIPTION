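Package: pseudotomo
Title: Pseudo-Subtomogram Averaging and Tilt-Series Refinement for
    Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subtomogram averaging for electron cryo-tomography built on a
    regularised likelihood that approximates the 2D tilt-image data model.
    Particles are represented as pseudo-subtomograms: 3D Fourier-space triplets
    of CTF-premultiplied data sums, squared-CTF sums and multiplicity counts.
    The package aligns and averages particles by expectation-maximisation with
    per-shell noise and signal power estimation, refines tilt-series optics
    (defocus, astigmatism, higher-order Zernike aberrations, dose-dependent
    damage scale factors) and geometry (rigid tilt alignment, spatially
    coherent per-particle 3D motion) against the average, and ships a fully
    synthetic tilt-series simulator so every estimator can be validated against
    known ground truth. Reads and writes RELION-dialect STAR tables and MRC2014
    volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
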