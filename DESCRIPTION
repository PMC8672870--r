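Package: fusim
Title: Hybrid Angular Spectrum Simulation of Focused Ultrasound in Heterogeneous Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end acoustic and thermal simulation of phased-array focused
    ultrasound in voxelized heterogeneous media. Builds synthetic gelatin /
    canola-oil phantom models, computes the source pressure of a 256-element
    phased array by the Rayleigh-Sommerfeld integral, propagates the beam with
    the split-step hybrid angular spectrum (HAS) method including reflection
    passes, converts pressure to deposited power density (Q = alpha p^2 / Z),
    solves the Pennes bioheat equation with an explicit finite-difference
    scheme, and quantifies agreement between fields with normalized RMSD,
    earth mover's distance, FWHM and center-of-thermal-mass metrics. An
    independent convergent Born series full-wave Helmholtz solver is included
    for steady-state cross-validation of the HAS propagator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
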