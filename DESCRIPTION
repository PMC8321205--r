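Package: lesionfuse
Title: Ensemble Decision Fusion for Skin-Lesion Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary melanoma / not-melanoma classification from RGB lesion
    photographs by crossing several feature representations with a bucket of
    probabilistic classifiers and fusing the per-image decisions through a
    mode-of-decisions, mean-of-modal-scores, argmax rule. Includes minority
    class balancing by K-means colour segmentation, transfer-learning style
    feature extraction with a deterministic offline encoder, a bootstrapped
    80/20 evaluation protocol, and a full confusion-derived metric suite
    (sensitivity, specificity, predictive values, F1, Matthews correlation).
    Ships synthetic image and feature generators so the whole pipeline is
    testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    graphics,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
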