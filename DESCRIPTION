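Package: seagrasstox
Title: Concentration-Response and Mixture Toxicity Analysis for PSII Herbicide Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for acute phytotoxicity bioassays that use pulse amplitude
    modulation (PAM) fluorometry endpoints, built around the miniature seagrass
    leaf assay. Computes effective and maximum quantum yields from raw
    chlorophyll fluorescence, applies leaf screening and control-drift quality
    control, fits four-parameter logistic concentration-response curves with
    multi-start nonlinear least squares, inverts them to ICx estimates with
    delta-method or bootstrap confidence intervals, computes relative potencies,
    runs extra-sum-of-squares F-tests between curves, performs Toxic-Unit /
    Concentration-Addition mixture analysis with an additive, synergistic or
    antagonistic classification, and compares ICx estimates against ecotoxicity
    threshold value guideline sets. A synthetic-assay generator reproduces the
    study design (12-well plates, nine replicate leaves per concentration,
    solvent controls, Toxic-Unit dilution series) so the whole pipeline is
    testable without laboratory data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
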