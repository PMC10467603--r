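Package: prognosig
Title: Prognostic Gene-Expression Signature Discovery for Stage II
    Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-cohort survival screening of gene expression,
    cut-off-based recurrence scoring, and beam-search refinement of
    prognostic gene signatures for relapse-free survival, modelled on
    signature discovery workflows for stage II colorectal cancer.
    Includes maximally selected log-rank cutpoint selection,
    Kaplan-Meier/log-rank/Cox evaluation reports, two-step NanoString
    nCounter count normalization with RLE/PCA quality control, and a
    synthetic multi-cohort data generator with planted proportional-
    hazards effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    pROC,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
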