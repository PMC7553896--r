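Package: radharm
Title: Settings-Profile Harmonisation, Reliability and Prognostic
    Screening for Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the seventeen radiomic features shared by the major
    feature-calculation platforms (shape, first-order intensity, histogram
    skewness, grey-level co-occurrence matrix and neighbourhood grey tone
    difference matrix features) from 3D volumes with binary region-of-interest
    masks, under configurable "settings profiles" that reproduce each
    platform's default calculation settings or a harmonised set. Assesses
    between-profile reliability with two-way mixed-effects absolute-agreement
    intraclass correlation coefficients (95% confidence intervals, negative
    truncation, four-category stratification) and screens standardised
    features against survival with univariable Cox regression, exposing how
    calculation settings alter both reliability and the direction of
    prognostic associations. Ships a synthetic phantom and cohort generator
    so the full analysis runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    yaml,
    Matrix,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
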