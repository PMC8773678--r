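Package: infarctCT
Title: Patch-Based Detection of Cerebral Infarcts on Non-Contrast Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for detecting hypodense cerebral infarcts
    on non-contrast head computed tomography volumes that have been resampled
    onto a common template grid. The pipeline enhances parenchymal contrast
    with an invertible piecewise Hounsfield-unit transformation, removes
    skull and cerebrospinal fluid by statistical thresholding, smooths with a
    stationary Gaussian kernel, and scores every voxel against a lesion-free
    control cohort with a single-case normative t statistic. Axial slices of
    the t-score map are tiled into 16x16 patches which a small convolutional
    neural network classifies as infarcted or non-infarcted; detections are
    localized by coordinate lookup in atlas label volumes. A seeded phantom
    generator produces control cohorts and lesioned patients with ground
    truth masks for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
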