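Package: fewviewct
Title: Few-View Fan-Beam CT Reconstruction with Weighted Total Difference
    Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative image reconstruction for few-view fan-beam computed
    tomography. Provides an analytic FORBILD-style head phantom, a Siddon
    ray-driven sparse system matrix, sinogram simulation with Gaussian
    measurement noise, and three reconstruction algorithms: SART, total
    difference minimization with soft-threshold filtering (TDM-STF), and
    weighted total difference minimization with soft-threshold filtering
    (WTDM-STF), the latter adding alpha-weighted diagonal difference terms
    that enforce directional gradient continuity. Includes FISTA-style
    acceleration, the RMSE/PSNR/NRMSD/NMAD image-quality metrics, 1D profile
    extraction, file round-tripping for images and sinograms, and an
    experiment runner that reproduces few-view comparison studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
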