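Package: thermex
Title: Thermal Expansion Survey of Organic Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes volumetric and principal thermal expansion coefficients
    for molecular crystals from variable-temperature unit-cell determinations.
    Builds structure families from a flat table of crystal-structure entries by
    Niggli cell reduction and a metric deformation measure, screens and
    deduplicates determinations, fits linear Lagrangian strain tensors
    referenced to 298 K, and characterises the population of coefficients with
    normal, skew-normal and two-half-normal distribution fits, 3-sigma
    exceptionality thresholds, negative-thermal-expansion classification and
    outlier tables. Includes a synthetic structure-database generator with
    planted ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
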