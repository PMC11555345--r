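Package: carsens
Title: Label-Free Cellular Senescence Indicators from Multiplex CARS
    Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for label-free detection of cellular
    senescence from multiplex coherent anti-Stokes Raman scattering (CARS)
    hyperspectral image cubes. Retrieves Im[chi3] spectra from raw CARS
    intensity by maximum-entropy-method phase retrieval with error-phase
    correction, calibrates the wavenumber axis, applies a two-stage
    baseline subtraction (mean outside-cell spectrum, then asymmetrically
    reweighted penalized least squares), decomposes the amide I band
    (1540-1740 cm-1) into purine, alpha-helix and beta-sheet Gaussian
    components, and computes the senescence indicator maps g2/(g1+g2) and
    g2-g1 together with per-cell nucleolar quantification, group
    statistics and size-ratio regression. A synthetic-data module
    generates labeled phantom cells and hyperspectral cubes with known
    composition so that every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    multcomp,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    withr
Config/testthat/edition: 3
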