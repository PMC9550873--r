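Package: sslheat
Title: Self-Supervised Patch Pretraining and Heatmap-Based Whole-Slide Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale diagnostic pipeline for whole-slide pathology
    images. Unlabeled tissue patches are used to pretrain a convolutional
    encoder with a bootstrap (online/target) self-supervised objective; the
    encoder is then fine-tuned with a linear head on labeled patches to
    produce per-patch malignancy probabilities. Patch probabilities are
    assembled into a slide-aligned probability heatmap, the heatmap is
    thresholded and summarized into a fixed 31-feature morphological vector
    (region counts, areas, perimeters, eccentricities, solidities and
    probability statistics), and a random forest issues the slide-level
    diagnosis. Includes a seeded generator of histology-like synthetic
    slides with exact ground-truth masks so the full pipeline is testable
    end to end, plus classification metrics (accuracy, balanced accuracy,
    sensitivity, specificity, Cohen's kappa, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
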