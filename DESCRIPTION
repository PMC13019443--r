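Package: sorsbone
Title: Supervised Reconstruction of Bone Raman Spectra from Transcutaneous
    Spatially Offset Raman Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for transcutaneous assessment of bone health with
    spatially offset Raman spectroscopy (SORS). Implements multi-response
    partial least squares (PLS2) regression, fitted with the SIMPLS
    algorithm, to reconstruct exposed-bone Raman spectra from paired
    transcutaneous measurements under leave-one-subject-out
    cross-validation; band-level biochemical metrics (mineral-to-matrix
    and phosphate-to-carbonate ratios, CH2 band width); DXA T-score
    regression with WHO bone-health classification, confusion-matrix
    metrics and pairwise ROC analysis; and a synthetic paired-spectra
    cohort generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
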