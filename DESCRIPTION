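Package: sabradiomics
Title: Radiomics Discrimination of Recurrence from Radiation-Induced Lung
    Injury After Lung SABR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a CT radiomics
    pipeline for distinguishing cancer recurrence from radiation-induced
    lung injury (RILI) at the moment a SABR-treated lung lesion triggers
    RECIST 1.1 progressive disease. Provides a synthetic CT phantom
    generator with planted class effects, RECIST line geometry and the
    progressive-disease rule, six RECIST-line-driven regions of interest
    (including a seeded graph-cut solid segmentation with ground-glass
    expansion), first-order/GLCM/GLRLM/shape feature extraction, a
    bootstrapped random-forest evaluation engine with correlation
    filters and out-of-bag operating points, and the accompanying
    statistical analyses (normality-routed group comparisons, biserial
    correlations, importance aggregation, single-feature ROC reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    nortest,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
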