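Package: wsigrade
Title: Quality Control, Scanner Appearance Migration and Patch-Based
    Gleason Grading for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for developing and evaluating patch-based
    Gleason grading models on whole-slide histology images. Provides
    tile-based image quality control (focus, contrast, saturation,
    artifacts, texture uniformity), per-channel probability-density
    matching to migrate images between scanner color spaces, annotation
    driven patch extraction with overlap-controlled sliding windows,
    a weighted multinomial patch classifier with incremental head-only
    updating, sliding-window slide inference with vote fusion and
    prediction simplification, and evaluation utilities including Gleason
    Grade Group derivation and quadratic weighted kappa. A seeded
    synthetic-fixture generator produces tissue-like images, scanner-style
    color shifts, quality degradations and partial polygon annotations so
    the whole pipeline is testable without any external slide data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
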