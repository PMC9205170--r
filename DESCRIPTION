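Package: organodx
Title: Organoid Drug-Response Profiling and Response-Signature Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for patient-derived organoid (PDO) chemotherapy
    response profiling. Fits four-parameter logistic dose-response curves and
    derives IC50, Emax and normalized AUC; classifies organoids into response
    categories and sensitive/resistant groups; scores xenograft efficacy with
    the percent tumor-growth-inhibition statistic; discovers predictive
    expression signatures by leave-one-out consensus differential expression
    and single-feature logistic-regression search; scores query signatures
    against reference rank profiles with a signed Kolmogorov-Smirnov
    connectivity statistic; and computes clinical concordance statistics
    (confusion metrics, Fisher's exact test, one-sided Cochran-Armitage trend
    test). Includes a synthetic-data generator that emulates the statistical
    structure of viability plates, RNA-seq count matrices, xenograft growth
    curves and patient cohorts, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    randomForest,
    e1071,
    rpart,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
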