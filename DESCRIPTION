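Package: carpo
Title: Quantification of Dynamic Wrist Movement from Real-Time MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying carpal kinematics from two-dimensional
    real-time MRI sequences of the moving wrist. The package covers the full
    processing chain: a synthetic articulated-wrist phantom with pixel-perfect
    ground truth, intensity normalization and biquadratic upsampling,
    multi-class U-Net semantic segmentation of eight forearm and carpal bone
    classes trained with a summed Dice and Hausdorff-distance loss,
    conditional-random-field and temporal label stabilization, algorithmic
    derivation of scapholunate and lunotriquetral gap widths along the carpal
    arc centerline, bounding-box wrist-angle estimation, and evaluation
    utilities (Dice similarity, Bland-Altman agreement, subject-level data
    splits, movement-cycle frame selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
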