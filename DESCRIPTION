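Package: leafpigments
Title: Non-Destructive Leaf Pigment Monitoring from Reflectance and
    Transmittance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring leaf pigments in controlled-environment
    plant experiments without destroying the leaf. Implements a
    generalized-plate leaf radiative-transfer forward model (PROSPECT-D
    style, extended with a xanthophyll-cycle carotenoid term), constrained
    nonlinear least-squares inversion of paired reflectance/transmittance
    spectra to estimate chlorophylls, carotenoids, anthocyanins and the
    zeaxanthin fraction, spectrophotometric wet-chemistry pigment
    quantification from ethanol extracts, light-adapted chlorophyll
    fluorescence quenching indices, and the downstream study analyses
    (area-to-mass unit conversion, grouped model-vs-assay correlation,
    pigment-ratio time series and photon-flux-density growth summaries).
    A synthetic-data generator reproduces the factorial design of a
    two-cultivar lettuce light-quality experiment so every pipeline stage
    can be exercised end to end.
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
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
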