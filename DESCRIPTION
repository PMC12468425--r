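Package: detfuse
Title: Ensemble Fusion and Statistical Evaluation of Bounding-Box Lesion Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic toolkit for combining and comparing object
    detectors in medical image analysis, motivated by endoscopic screening
    for Barrett's esophagus where missed lesions are costlier than false
    alarms. Pools bounding-box predictions from several detectors and fuses
    them with a single joint non-maximum suppression pass; evaluates
    detectors against expert annotations by IoU-threshold one-to-one
    matching with micro-averaged precision, recall and F1; builds ensembles
    by greedy recall-first forward selection; and compares paired systems
    with McNemar's exact test, stratified image-level bootstrap confidence
    intervals for recall differences, and a z-like error-rate P-score.
    Includes a synthetic multi-detector study generator with controllable
    sensitivity, false-positive rate, localization jitter and cross-detector
    miss correlation, plus readers and writers for YOLO-format label files,
    a manifest CSV and a COCO-style JSON dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
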