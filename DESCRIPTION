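Package: npkspec
Title: Hyperspectral Diagnosis of Leaf Nitrogen, Phosphorus and Potassium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for diagnosing nitrogen, phosphorus and
    potassium content in crop leaves from visible/near-infrared reflectance
    spectra. Provides a synthetic leaf-spectra generator for three nitrogen
    fertilisation treatments, radiometric correction against white/dark
    references, extraction of 24 classical spectral characteristic variables
    (edge amplitudes and positions, green peak, red valley, edge areas and
    vegetation indices), an undecimated dyadic wavelet decomposition (db2-db5,
    five levels) with correlation-based selection of wavelet sensitivity
    coefficients, univariate (linear, parabolic, exponential, logarithmic),
    partial least squares and single-hidden-layer neural-network calibration
    models, and an AHP-weighted composite evaluation score combining R-squared,
    mean relative error and normalised RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    nnet,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
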