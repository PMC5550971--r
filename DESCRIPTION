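Package: lvbiomech
Title: Biomechanical Biomarkers of Left-Ventricular Contractile Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale pipeline for biomechanical biomarker analysis of the
    left ventricle after acute myocardial infarction. Implements the
    Holzapfel-Ogden passive myocardial law with an infarct-extent field,
    active tension with myofilament kinetics, a reduced-order
    truncated-ellipsoid left-ventricle model with rule-based fibers, inverse
    estimation of patient-specific contractility from cavity volume and 24
    segmental circumferential strains, a calibrated synthetic cohort
    generator, a nested leave-one-out cross-validated eight-classifier study
    with ROC convex-hull AUROC and factor-importance rank fusion, and
    association analysis between baseline biomarkers and six-month outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    class,
    glmnet,
    rpart,
    randomForest,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
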