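Package: thymil
Title: Divide-and-Conquer Attention-Based Multiple Instance Learning for
    Thymoma Whole-Slide Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of thymoma whole-slide images
    into the five WHO subtypes (A, AB, B1, B2, B3) using gated attention-based
    multiple instance learning arranged as a divide-and-conquer hierarchy
    (lymphocyte-poor {A, B3} versus lymphocyte-rich {AB, B1, B2}, then binary
    and ternary refinement), with pseudo-label-driven refinement of a shared
    patch encoder.  Includes slide tiling with saturation-based tissue
    masking, multi-class patch heatmaps from an auxiliary patch classifier,
    nucleus morphology statistics (Kruskal-Wallis, Dunn's post hoc test with
    Benjamini-Hochberg adjustment, significance star grading), instance
    segmentation evaluation metrics (Dice, AJI, panoptic quality), and a
    synthetic slide/cell phantom generator so that every stage is testable
    without access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
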