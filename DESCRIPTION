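Package: alphaRECIST
Title: Composite AFP-Imaging Response Criteria with Survival Validation
    for Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating radiological tumor response in
    hepatocellular carcinoma treated with conversion radiotherapy.
    Implements RECIST 1.1 and mRECIST category engines, a family of
    composite criteria that combine size-based response with serum
    alpha-fetoprotein (AFP) change or baseline level (including the
    alpha-RECIST rule: responder if RECIST 1.1 partial or complete
    response, or AFP decrease of at least 76 percent), survival-based
    cutoff discovery by maximally selected log-rank statistics with
    selection-bias correction, Kaplan-Meier, log-rank and univariate Cox
    validation, weighted-kappa inter-reader agreement, pathologic
    response concordance, and a calibrated synthetic cohort generator so
    every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
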