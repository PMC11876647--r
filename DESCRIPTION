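Package: lcspp
Title: Long-Term Cross-Sensor Reflectance Calibration and SIF-Informed
    Photosynthesis Proxy Reconstruction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building a multi-decadal, cross-sensor consistent
    red/near-infrared reflectance record and a solar-induced fluorescence
    (SIF) informed photosynthesis proxy from it.  The package harmonizes a
    drifting multi-sensor reflectance stream against a stable reference
    sensor (pseudo-invariant site bias proxies, solar-zenith-angle drift
    regression, windowed pixel-wise linear calibration, and a residual
    neural network on environmental covariates), gap-fills with seasonal
    means and harmonic analysis of time series (HANTS), emulates satellite
    SIF from two reflectance bands plus solar geometry with a small
    feedforward network, derives instantaneous clear-sky, daily clear-sky
    and daily all-sky proxy layers, and validates the result with
    pseudo-invariant site diagnostics, vegetation-index baselines,
    Theil-Sen and modified Mann-Kendall trend tests and site-level GPP
    comparisons.  A fully parameterized synthetic-scene generator with
    retained ground truth supports parameter-recovery testing of the whole
    chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
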