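Package: wormscope
Title: Whole-Plate C. elegans Detection, Segmentation and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and counting Caenorhabditis elegans on whole
    Petri-dish brightfield images. Provides dish localization and background
    masking, sliding-window tiling of large plate images, a classical
    adaptive-threshold and morphology segmentation chain with shape-descriptor
    blob filtering, post-processing of externally produced detections
    (confidence and size filters, per-class non-maximum suppression), and the
    standard object-detection evaluation protocol (greedy IoU matching,
    precision/recall/F1, interpolated average precision, IoU threshold
    sweeps). A synthetic dish-image generator with exact per-worm ground
    truth makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
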