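Package: mridense
Title: Volumetric Breast Density Quantification from Breast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantifying breast density from
    T1 fat-saturated pre-contrast breast MRI. Assembles DICOM series into
    canonically oriented, z-score normalized 3D volumes; segments the breast
    and its fibroglandular (dense) tissue with a compact 3D V-Net applied by
    patch-based sliding-window inference with overlap averaging; computes the
    volumetric density ratio (dense voxels over breast voxels) with
    contralateral-breast selection; maps free-text mammography reports to the
    four-level ordinal density scale by keyword rules; and analyses the
    concordance between MRI-derived density and report categories (Spearman,
    tie-corrected Kendall tau-b, single-feature ordinal classification).
    Ships a synthetic breast-phantom generator so the whole pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
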