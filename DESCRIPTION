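Package: mitomotion
Title: Quantification of Mitochondrial Motility and Morphology in
    Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated pipeline for quantifying organelle motility and
    morphology in calibrated 2-D time-lapse fluorescence movies of neuronal
    mitochondria. Provides translation drift correction, Laplacian-of-Gaussian
    spot detection with sub-pixel localization, optimal frame-to-frame particle
    linking without gap closing, first-frame binary morphometry (area, Feret's
    diameter, aspect ratio), the motile-fraction statistic, nonparametric group
    comparison (tie-corrected Kruskal-Wallis with Dunn's post hoc test on
    preselected pairs), and a synthetic-movie generator with ground-truth
    tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
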