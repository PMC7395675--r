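Package: oct2vf
Title: Structure-Function Mapping from Peripapillary OCT to Visual Field
    Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling the structure-function relationship in
    glaucoma from paired imaging and perimetry data. Implements a small
    one-dimensional convolutional network that regresses the 52 sensitivity
    thresholds of a 24-2 visual field onto the 768 peripapillary retinal
    nerve fiber layer (RNFL) thickness samples of an OCT circle scan,
    together with an ordinary-least-squares baseline, the cohort curation
    rules (test pairing, reliability and quality filters, patient-level
    splits), localized RNFL defect simulation at population percentile
    depths, visual-field report derivation (total and pattern deviation,
    probability maps, global indices), evaluation statistics with
    cluster-bootstrap and mixed-model comparisons, and assembly of a
    structure-function map from simulated defects. A synthetic paired-exam
    cohort generator with a known nonlinear forward model provides ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
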