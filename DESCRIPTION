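Package: murilung
Title: Lung Nodule Detection Pipeline for Murine Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automated detection of lung nodules in
    micro-CT scans of mice. Provides rule-based lung segmentation from
    Hounsfield-unit volumes, training-data augmentation by inserting synthetic
    tumors into scans through cone-beam forward projection and FDK
    reconstruction, a compact volumetric V-Net-style convolutional network
    trained with a Dice loss, and detection post-processing with
    precision/recall/Dice metrics, threshold sweeps and size-binned detection
    rates. A built-in digital mouse-thorax phantom generator makes every stage
    testable without any real scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
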