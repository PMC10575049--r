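Package: ipmnet
Title: Interferometric Plasmonic Microscopy Simulation and Y-Net Scatterer
    Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of interferometric plasmonic microscopy (iPM)
    images -- a plane reference wave interfering with the decaying
    surface-plasmon leakage wave scattered by point objects on a thin metal
    film -- together with a multi-task Y-Net convolutional network that
    localizes nanoscale scatterers to a single pixel, regresses their
    amplitude and phase, estimates six image-wide optical variables, and
    re-renders a noise-free reconstruction of the input image. Includes a
    seeded synthetic-data generator with Gaussian blur and white-noise
    augmentation, a weighted binary cross-entropy loss for sparse single-pixel
    targets, an Adam/cosine-annealing training loop, and evaluation of
    localization accuracy within the diffraction limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tidyr,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
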