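Package: silksims
Title: Subcellular Isotope Turnover from Correlated SEM and NanoSIMS Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies 13C-glucose incorporation and turnover in neuronal
    subcellular compartments from correlated scanning electron microscopy
    (SEM) and NanoSIMS isotope imaging. Provides drift alignment and
    accumulation of multi-plane ion-count rasters, per-mil delta-13C maps
    with Poisson counting errors, landmark-based affine registration of the
    SEM and NanoSIMS frames, region-of-interest quantification on the native
    ion-count grid, pulse-chase turnover kinetics, mitochondrial morphometry
    and mitochondria-ER contact counting, group statistics, and a calibrated
    synthetic forward model so the full chain can be exercised and validated
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
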