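Package: vmatqa
Title: Virtual Patient-Specific QA for VMAT Plans with MLC Leaf-Position Maps
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measurement-free ("virtual") patient-specific quality assurance
    for single-arc VMAT treatment plans. Builds the MLC leaf-position map
    (MLPM) -- a 2D image of leaf displacement from the closed state, leaves by
    control points -- from DICOM RT-Plan files, extracts fixed-size dose
    planes through the isocenter from RT-Dose grids, computes global
    gamma-index passing rates at the nine 1-3%/1-3mm criteria, and trains a
    lightweight multi-branch convolutional network that predicts the nine
    gamma passing rates of a plan directly from the MLPM and dose planes.
    Includes a synthetic plan/dose/delivery-error simulator so the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
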