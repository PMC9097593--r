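Package: phasetrack
Title: Tracking and Motility Quantification for Phase-Contrast Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of amoeboid cell motility from
    phase-contrast time-lapse microscopy. Implements two preprocessing
    pipelines (cell-shape enhancement by LUT inversion and local background
    subtraction; contractile-vacuole spot enhancement by log transform,
    inversion, rolling-ball background subtraction and Gaussian blur),
    thresholded centroid and sub-pixel spot detection, optimal-assignment
    trajectory linking with gap closing, two-timescale velocity statistics
    with exact Mann-Whitney group comparison, and kymograph-based colony
    front-speed fitting and step detection. Ships a synthetic time-lapse
    generator (persistent random walks, leader-follower chains, advancing
    fronts) with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
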