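Package: fhdx
Title: Clinical Diagnostic Criteria, Treatment-Intensity Correction and
    LDLR Variant Spectrum Analysis for Familial Hypercholesterolemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating clinical diagnostic criteria for familial
    hypercholesterolemia (FH) against genetic results. Implements the Dutch
    Lipid Clinic Network score and its Chinese-modified LDL-C bands, the
    Simon Broome Register, MEDPED, Japanese FH Management Criteria and the
    Hong Kong expert-panel recommendation; estimation of untreated LDL-C
    from on-treatment values via statin/ezetimibe treatment-intensity
    multipliers; diagnostic-performance statistics (confusion matrices,
    Fisher exact tests, ROC/AUC and Youden-optimal cutoffs) including an
    exhaustive integer confusion-matrix reconstruction from rounded
    published metrics; HGVS cDNA parsing and receptor-class tallying of
    LDLR variant spectra; and a reproducible synthetic cohort generator
    emulating the structure of a proband plus cascade-screening study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
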