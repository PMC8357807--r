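Package: macroscreen
Title: Colorimetric Electron-Uptake Screen and Bioelectrochemical
    Validation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide electron-uptake screens in
    Shewanella oneidensis read out by oxidation of the redox dye
    AHDS_red. Quantifies plate photographs of 96-well assays via a
    white-referenced normalized yellow-intensity score, decodes Code 128
    plate barcodes with registration-mark grid localization, runs
    growth-plate quality control against a collection catalog, estimates
    dye-oxidation rates and calls slowed/eliminated mutants against
    quasi-wild-type controls, and analyzes potentiostat validation data:
    biological cathodic currents from chronoamperometry (pre/post
    respiratory-inhibitor difference of final-100-point steady states)
    and midpoint potentials from cyclic voltammetry (cubic smoothing
    spline, approximate derivative, forward/reverse inflection
    averaging), with strain comparison by type-II ANOVA and Tukey HSD.
    Includes a synthetic-data generator producing plate images, catalogs
    and potentiostat traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
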