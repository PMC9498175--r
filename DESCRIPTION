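Package: grainscan
Title: Grain Morphometry and Quality Grading from Flatbed-Scanner Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for grading rice samples scanned on a
    calibrated flatbed scanner. Converts pixels to millimetres with a
    reference-disk (pixels-per-metric) calibration, segments individual
    kernels on a dark background, measures kernel length and width from the
    midpoints of the minimum-area rotated bounding box, scores yellowness and
    chalkiness as HSV in-range pixel fractions, flags damaged and paddy
    (unhulled) kernels with pluggable binary classifiers, predicts per-kernel
    weight with a random-forest regressor on length and width, and assembles
    a sample-level quality report (average grain length and width, head-rice
    statistics, broken-kernel grading, length histogram with percent by
    weight). A deterministic synthetic-scene generator renders scanner-like
    images with exact ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    glmnet,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
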