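Package: leukodiag
Title: Blood-Smear Microscopy Analysis for Acute Lymphoblastic Leukemia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical image-analysis pipeline for screening stained blood-smear
    micrographs for acute lymphoblastic leukemia. Provides image enhancement by
    combined average and Laplacian filtering, adaptive region-growing segmentation
    of lymphocyte nuclei with morphological refinement, hybrid texture and color
    descriptors (local binary patterns, gray-level co-occurrence statistics, and a
    fuzzy color histogram) fused into a 232-entry feature vector, multilayer
    perceptron and max-margin classifiers with validation-based early stopping, a
    small trainable convolutional network usable as a deep-feature extractor, a
    full evaluation suite (confusion matrix, accuracy/precision/sensitivity/
    specificity, ROC/AUC, error histogram, regression R), stratified splitting and
    class-balanced augmentation, and a deterministic synthetic smear generator
    with ground-truth nucleus masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    yaml,
    optparse,
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
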