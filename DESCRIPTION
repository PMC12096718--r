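Package: firstdose
Title: First-Dose Beta-Lactam Exposure and Target Attainment in Critical Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing plasma target attainment of beta-lactam
    antibiotics (meropenem, piperacillin) during the first dosing interval of
    loading-dose plus extended-infusion regimens in intensive-care patients.
    Implements two-compartment infusion pharmacokinetics with closed-form
    superposition, maximum a posteriori (MAP) Bayesian estimation of individual
    parameters from sparse therapeutic drug monitoring samples, percent fT>MIC
    target-attainment metrics, renal-function assessment (CKD-EPI 2021,
    Cockcroft-Gault, augmented renal clearance scoring, KDIGO acute kidney
    injury), trough-to-peak ratio analysis with ROC-derived cutoffs, and a
    synthetic-cohort generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
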