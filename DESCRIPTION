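Package: boct
Title: Spectral-Domain OCT Biometry of Ocular Axial Dimensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator-backed implementation of OCT biometry: measurement of
    ocular axial dimensions (axial length, anterior chamber depth, lens
    thickness, central corneal thickness) with a spectral-domain OCT device
    using four C-gate-shifted measurement windows. Provides a layered eye
    phantom with pathology models (lens opacity shadowing, RPE elevation,
    retinal detachment), a spectral-fringe A-scan/B-scan simulator with
    sensitivity roll-off and speckle, automatic boundary segmentation with
    manual correction, robust outlier rejection over repeated shots,
    optical-path to geometric-distance conversion via group refractive
    indices, a glass-block accuracy check, and the full precision and
    agreement statistics toolkit for test-retest studies: within-subject
    standard deviation, test-retest repeatability, coefficient of variation,
    one-way intraclass correlation, Bland-Altman limits of agreement and
    paired t-tests, plus scripted repeatability and device-agreement study
    runners on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
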