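Package: resistsig
Title: Detecting Drug-Resistance-Associated Transcriptional States in
    Single-Cell Drug-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus drug-resistance gene signatures from ranked
    differential-expression lists by robust rank aggregation, scores
    single cells for signature activity with an area-under-the-recovery-curve
    (AUCell-style) statistic and an expression-matched control-geneset
    activity threshold, calls resistance-activated clusters (RACs) by Fisher
    exact odds ratio, groups RACs across cell lines into superclusters on
    Spearman correlation of differential mean-expression vectors, validates
    signatures on bulk cohorts with single-sample GSEA and Cox proportional
    hazards, and ships a synthetic-data generator with planted ground truth
    so the whole pipeline is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    survival,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
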