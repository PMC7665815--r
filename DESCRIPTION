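Package: liradscat
Title: LI-RADS v2018 Categorization and Diagnostic Accuracy of Adjusted LR-5 Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic rule engine for the Liver Imaging Reporting and
    Data System (LI-RADS) v2018 categorization of hepatic observations on
    gadoxetate-enhanced MRI, together with six modified criteria that upgrade
    or demote categories (ancillary-feature upgrades of LR-4, arterial-phase
    hyperenhancement read on subtraction images, washout conditioned on
    wash-in, transitional-phase washout, and v2017-style threshold growth).
    Includes paired diagnostic-test-accuracy machinery (sensitivity,
    specificity, predictive values and accuracy with exact Clopper-Pearson
    intervals, exact McNemar tests, binary-rule ROC AUC with correlated
    DeLong comparison), a deterministic reconstruction of a 792-observation
    reference cohort, a stochastic cohort simulator for property testing,
    and a reporting pipeline.
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
    pROC
Config/testthat/edition: 3
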