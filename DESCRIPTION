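Package: senotec
Title: Endothelial-Senescence Signature Derivation and Prognostic Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a tumor-endothelial-cell (TEC) senescence gene signature
    from multiple single-cell RNA-seq datasets and evaluates it prognostically
    in bulk cohorts. Implements single-sample gene-set enrichment scoring via a
    rank-based random-walk statistic, Wilcoxon marker detection with
    percent-expressed and log-fold-change filters, per-dataset senescence
    correlation evidence, a cross-dataset geometric-mean consensus procedure,
    and a downstream Cox risk score with median dichotomization, Kaplan-Meier
    estimation and the log-rank test. A synthetic single-cell and bulk cohort
    generator with planted ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    survival,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
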