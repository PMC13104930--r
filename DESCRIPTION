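Package: pafunmix
Title: Photoacoustic Fingerprinting for Multispectral Chromophore Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative spectral unmixing of multispectral
    photoacoustic data. Treats the vector of per-wavelength photoacoustic
    amplitudes as a molecular "fingerprint" and estimates chromophore
    concentration fractions (oxy- and deoxyhemoglobin, lipid, water,
    collagen) either by a recurrent neural network trained on synthetic
    fingerprints spanning realistic mixtures, fluence distortions and noise
    levels, or by a non-negative least squares baseline. Includes a
    spectral-library builder on a dual-band near-infrared wavelength grid,
    a physics-driven fingerprint simulator with an exponential fluence
    prior and SNR-calibrated Gaussian noise, parity and error metrics,
    oxygen-saturation mapping, and an end-to-end pipeline turning
    multispectral image stacks into per-pixel concentration maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
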