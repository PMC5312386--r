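Package: wntitr
Title: RNAi Screen Hit Calling, Regulator Inference and beta-Catenin
    Signature Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for plate-based RNAi viability screens and
    downstream regulator analysis in neuroblastoma. Implements loess-based
    spatial normalization of 384-well plates fitted on sample wells only,
    robust z-scores, Huber Proposal 2 winsorized scale estimation and
    three-sigma hit calling; inferred-transcriptional-regulator (ITR)
    scoring of differential-expression results against a signed
    regulator-target network (hypergeometric overlap p-value and
    activation z-score); construction of a beta-catenin target-gene
    signature from per-contrast contributing genes; MYCN-expression
    correction of tumour expression matrices by linear-model covariate
    subtraction; hierarchical-clustering group assignment with an
    MYCN-amplification separation F-test; and Kaplan-Meier / log-rank
    patient stratification with Spearman correlation utilities. Ships
    synthetic-data generators with planted ground truth emulating each
    input, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
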