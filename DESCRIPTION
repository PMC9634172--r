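Package: chordomaTIME
Title: Tumor-Immune Microenvironment Analysis for Multiplex Immunofluorescence of Chordoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell tables exported from multiplex
    immunofluorescence (MIF) imaging of chordoma and other solid tumors.
    Provides per-specimen marker gating into myeloid, T-cell and NK
    phenotypes, tumor/stroma compartmentalization from annotations or from
    cytokeratin-positive cell density, per-compartment density quantification
    with a ratio-based parenchymal inclusion/exclusion classifier,
    nearest-neighbor and radius/band proximity statistics, cohort-level
    hypothesis tests, and a marked point-process tissue simulator with planted
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    mgcv,
    mclust,
    car,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
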