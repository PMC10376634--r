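Package: codaseg
Title: Co-Training with Class-Wise Distribution Alignment for
    Semi-Supervised Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised semantic segmentation by cross-pseudo
    supervision between two differently initialized networks, with
    class-wise alignment of the marginal prediction distributions on
    unlabeled data to those on labeled data, and an over-expectation
    cross-entropy loss that filters low-confidence pseudo-labels with
    dynamic per-class thresholds. Includes exponential-moving-average
    estimation of class-conditional prediction distributions, a
    temperature-scaled coefficient transformation of unlabeled
    predictions, a lightweight trainable per-pixel segmentation
    backbone, surface-distance evaluation metrics (mIoU, Dice,
    Jaccard, ASD, Hausdorff and 95th-percentile Hausdorff), a
    reproducible generator of imbalanced multi-class synthetic
    segmentation tasks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
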