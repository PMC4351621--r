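Package: exresponse
Title: Sensitivity-First Prediction of Clinical Drug Response from Ex Vivo
    Tumour Explant Read-Outs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage ordinal classification of clinical response (NR, PR,
    CR) from four ex vivo tumour-explant functional read-outs (viability,
    histology, proliferation, apoptosis).  Stage one learns a linear score
    by maximizing the partial area under the ROC curve up to a false
    positive rate budget (a structural-SVM-style ranking objective) and
    places a responder threshold that spends at most that budget on the
    training set; stage two adds a second threshold separating partial from
    complete responders by maximizing PR/CR accuracy.  Ships the frozen
    published coefficients and thresholds as an executable scorer, a
    support vector ordinal regression baseline, single-read-out baselines,
    a synthetic patient-cohort generator for validating the pipeline, and
    ROC, partial-AUC and confusion-matrix evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
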