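Package: catransient
Title: Analysis of Intracellular Calcium Transients from Fluorescence Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete analysis workflow of intracellular Ca
    transients recorded with fluorescent indicators: preparation of raw
    fluorescence (background subtraction, ratiometric ratios, calibration to
    absolute calcium concentration via the indicator dissociation constant,
    and F/F0 pseudo-ratio normalization), measurement of diastolic, systolic
    and amplitude levels, and kinetic analysis of the transient decay by
    single- and double-exponential nonlinear least-squares regression with
    heuristic initial parameter prediction and adjusted R-squared nested
    model comparison. Includes a seedable synthetic transient generator for
    validation, a collated-results pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    tidyr,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    jsonlite,
    rlang,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
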