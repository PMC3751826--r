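Package: cardioflow2d
Title: Moving-Domain Hemodynamics of the Embryonic Heart in Two Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-to-hemodynamics toolkit for valveless embryonic hearts.
    Turns time-resolved endocardial boundary traces into prescribed wall
    motion, triangulates the moving lumen, advances the incompressible
    Navier-Stokes equations on the deforming mesh with an arbitrary
    Lagrangian-Eulerian (ALE) stabilized equal-order finite-element method,
    and post-processes the flow into wall shear stress, chamber pressure
    gradients, stream functions, ejection fraction, and Reynolds/Womersley
    numbers. Includes an FFT cross-correlation particle image velocimetry
    (PIV) module for inlet velocimetry from fluorescent blood-cell videos,
    and synthetic generators for peristaltic-tube and two-chamber wall
    motion with known-flow particle videos for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
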