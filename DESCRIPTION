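Package: protomorph
Title: Whole-Skull Geometric Morphometrics for Socio-Sexual Signalling Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing socio-sexual signalling predictions on 3D
    landmark data from fossil skulls, built around the ceratopsian
    parietal-squamosal frill. Implements generalized Procrustes alignment with
    reflection augmentation across the sagittal plane, thin-plate-spline
    semilandmark sliding, maximum-likelihood modularity analysis of landmark
    congruence matrices with AICc model comparison and a covariance-ratio
    permutation test, common-allometric-component and module centroid-size
    allometry with ANCOVA slope comparisons, per-landmark and per-module
    Procrustes variance (disparity), and Hartigan's dip test scans of residual
    shape components for shape dimorphism. Includes a synthetic landmark-data
    generator with planted modular covariance, module-specific allometry,
    optional dimorphism and taphonomic compression, so every stage of the
    pipeline can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
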