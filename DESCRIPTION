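Package: ramancoat
Title: Core-Independent PLS Calibration for Inline Raman Monitoring of
    Tablet Film Coating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric pipeline for predicting applied coating mass during
    pharmaceutical tablet film coating from inline Raman spectra. Implements
    core-spectrum subtraction (differential spectra), standard normal variate
    and Savitzky-Golay preprocessing, end-point "max"/"max3" normalization,
    partial least squares calibration by NIPALS with Hotelling T-squared
    outlier exclusion and spectral-range/factor optimization, calibration
    transfer of a single-core model to other tablet cores, end-point coating
    thickness estimation for biconvex tablets, and a synthetic coating-run
    generator that emulates the spectral structure of inline coating
    measurements so the whole chain is testable without instrument data.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
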