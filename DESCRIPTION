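Package: vesselseg
Title: Retinal Vessel Segmentation with a Double-Branch Fusion U-Net and
    Hard-Example Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pixel-level retinal vessel segmentation in fundus
    photographs. Implements morphology-based hard-example mask extraction
    from vessel ground truth and the associated weighted cross-entropy
    loss, a random channel attention (RCA) stochastic regularizer, and a
    double-branch fusion U-Net (shared encoder, two decoders, fusion
    layer) trained with a staged schedule in which one decoder emphasizes
    hard pixels. Includes green-channel/CLAHE preprocessing, geometric and
    elastic augmentation, field-of-view restricted evaluation (F1,
    sensitivity, specificity, accuracy, G-mean, MCC, AUC) with gray-level
    threshold selection, and a seeded synthetic fundus generator so the
    full pipeline runs end-to-end on CPU without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    EBImage,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
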