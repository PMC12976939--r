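Package: neutrocount
Title: Neutrophil Counting and Infection Diagnosis in Whole-Slide Histology
Version: 0.1.0
Authors@R: person("neutrocount", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrated high-powered-field tiling of whole-slide histology
    images, sliced (sliding-window) small-object detection with cross-window
    merging, IOU-based detection evaluation, and median-per-field diagnostic
    classification of periprosthetic joint infection, together with an exact
    McNemar comparison of paired classifiers. Ships a deterministic synthetic
    H&E-like tile and case generator plus a rule-based reference neutrophil
    detector so the full pipeline is testable without trained weights or
    clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
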