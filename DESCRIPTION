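Package: ctohybrid
Title: Complexity Scores and Diagnostic Accuracy for Hybrid Chronic Total
    Occlusion PCI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes five chronic total occlusion (CTO) lesion-complexity
    scores (CT-RECTOR, KCCT, J-CTO from CCTA, RECHARGE from CCTA, and the
    angiographic J-CTO) from per-lesion imaging and clinical features,
    derives the procedural endpoints of hybrid-algorithm CTO PCI
    (time-efficient guidewire crossing, final procedural success, need for
    any non-antegrade-wiring strategy), and compares the scores'
    diagnostic accuracy with ROC/AUC analysis using the DeLong method,
    Youden-index cutpoints, Cohen's kappa, Fisher exact and rank tests.
    Includes a deterministic 110-lesion count fixture and a latent-difficulty
    synthetic cohort generator so the whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
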