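Package: dateqi
Title: Storage-Quality Indexing and VIS-NIR Chemometrics for Date Fruits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for postharvest storage-quality analysis of date fruits
    (Tamr stage). Computes CIELAB colour derivatives (chroma, hue angle,
    browning index, total colour difference), builds a normalized composite
    quality index (Qi) from physicochemical and sensory attributes, fits and
    compares linear and quadratic storage-degradation models (AIC and nested
    F-test), and calibrates spectra-to-Qi predictors from 410-990 nm VIS-NIR
    reflectance: windowing, absorbance conversion, multiplicative scatter
    correction, Savitzky-Golay second derivatives, replicate-aware 70/20/10
    splitting, NIPALS partial least squares regression with grouped
    cross-validation, a feed-forward neural-network regressor, and the full
    figure-of-merit suite (R2, RMSEC, RMSECV, RMSEP, REP, RER). Includes a
    synthetic storage-study generator emulating the full factorial design so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    signal,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
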