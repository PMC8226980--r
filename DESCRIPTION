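Package: vesselflow
Title: Hemodynamics Simulation and Velocimetry for Serpentine Vessel-on-a-Chip Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale reimplementation of the computational workflow behind a
    serpentine tumor vessel-on-a-chip: channel planform construction with
    thrombus (clot) and hemorrhage (wall-gap) defects, Carreau shear-thinning
    blood rheology, a depth-averaged Stokes-Brinkman flow solver with
    wall-shear-stress estimators, synthetic tracer-bead and red-blood-cell
    speckle image generation, particle tracking with trajectory statistics
    (mean speed, scattering angle, wall-interaction length), and label-free
    micro-particle image velocimetry by normalized cross-correlation template
    matching.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
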