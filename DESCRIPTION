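Package: wristadl
Title: In-the-Wild Activity-of-Daily-Living Recognition from Dual-Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recognizing activities of daily living (ADLs) in
    long, unscripted dual-wrist accelerometer recordings dominated by a NULL
    (background) class. Provides sliding-window segmentation and a
    106-dimensional time/frequency feature representation, imbalance-aware
    training (random undersampling, ratio-preserving random oversampling,
    cost-sensitive class weights) for classical window classifiers,
    context-based correction of prediction streams with distance-weighted
    voting, event-level precision/recall/F1 built on Ward-style event
    categories (correct, insertion, deletion, fragmentation, merge), and a
    synthetic stream generator that emulates the extreme class imbalance of
    in-the-wild recordings so the full pipeline can be exercised without
    access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
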