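Package: cbctrisk
Title: Imaging Dose and Secondary-Cancer Risk for Cone-Beam CT Acquisition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes organ equivalent dose, ICRP-103 effective dose and BEIR VII
    excess absolute risk (EAR) of secondary cancer incidence from kilovoltage
    cone-beam CT (CBCT) imaging-dose grids or organ mean-dose tables. Includes
    acquisition-protocol mAs arithmetic and Monte-Carlo-style calibration-factor
    scaling for thorax, pelvis and 4D-CBCT modes, voxel dose-grid and organ-mask
    containers with mean-dose extraction and portable grid I/O, a synthetic
    rotational kV dose simulator with half-bowtie and heel-effect beam
    asymmetries, a body-phantom and patient-cohort generator with BMI
    stratification, and report assembly for organ-dose, effective-dose and
    EAR-versus-time summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
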