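Package: mirtam
Title: Integrative miRNA-mRNA Regulatory Analysis of Tamoxifen Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for inferring functional miRNA-target
    relationships in tamoxifen-resistant breast cancer cell line models.
    Provides signal-dependent quantile-spline normalization of qPCR
    crossing-point (Cp) matrices with melting-curve quality control,
    exact-match quantification of small-RNA sequencing reads against a
    mature miRNA reference, moderated differential expression with a
    cross-cell-line sign-consistency signature, inverse-correlation
    inference of predicted functional miRNA targets gated by multi-tool
    target predictions, signed Wilcoxon target-enrichment statistics and
    regulation-accounting odds ratios, and cross-cohort logistic/ROC
    evaluation of miRNA recurrence classifiers. A synthetic-data module
    generates every input with planted ground truth (regulatory edges,
    plate-level signal-dependent Cp bias, decoy target predictions,
    outcome effects) so each stage of the pipeline can be validated
    against a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
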