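Package: speckleflow
Title: Diffuse Speckle Contrast Analysis for Deep Tissue Blood Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward modelling and processing tools for diffuse speckle
    contrast analysis (DSCA/SCOS) with photon-counting SPAD cameras.
    Computes the semi-infinite correlation-diffusion field autocorrelation
    and exposure-integrated speckle contrast, models photon-counting
    acquisition timing, simulates gamma-Poisson speckle frame stacks with
    dark counts and hot pixels, and implements the shot-noise-corrected
    speckle contrast to blood-flow-index pipeline with downstream Welch
    spectral, envelope-trend and baseline-change analyses.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    tiff,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
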