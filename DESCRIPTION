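Package: ccseg
Title: Centroid-Crop Self-Training for Lesion Segmentation in Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Teacher-student self-training for binary lesion segmentation in
    grayscale radiographs, built around centroid cropping-based sampling (CCS):
    fixed-size patches are extracted around the centroids of mask foreground
    components so that training data are freed from the extreme
    foreground/background pixel imbalance typical of small lesions in large
    frames.  Provides LabelMe-style polygon annotation rasterisation, a seeded
    synthetic radiograph generator, a deterministic five-way joint
    image/mask augmentation scheme, segmentation metrics (mean pixel accuracy,
    IoU, Dice) with micro and per-image aggregation, a small fully
    convolutional encoder-decoder backbone trainable on a CPU, and an
    experiment runner for labelled/pseudo-labelled budget sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
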