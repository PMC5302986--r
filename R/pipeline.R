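#' Bundled qPCR log2 fold-change signature table
#'
#' The 22-miRNA signature measured by LNA-based qPCR in the tamoxifen
#' resistance cell line model: log2 fold changes of each miRNA in the three
#' resistant lines (TamR1, TamR4, TamR8) relative to the parental
#' MCF-7/S0.5 line. Every row is significant at adjusted p < 0.05 in all
#' three contrasts; the table ships with the package as a worked example
#' for [consistent_signature()] and [select_candidates()].
#'
#' @return data.frame with column `mirna` and one log2FC column per
#'   resistant line.
#' @export
tamr_qpcr_signature <- function() {
  path <- system.file("extdata", "tamr_qpcr_log2fc.tsv", package = "mirtam",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Wrap a printed log2FC table as differential-expression results
#'
#' Builds one [de_test()]-shaped result per fold-change column of a table
#' whose rows are all significant (the published signature tables carry no
#' p-values; significance is asserted by their caption). The supplied
#' `padj` is attached to every feature.
#'
#' @param tab data.frame with a `mirna` (or first) id column and one
#'   numeric log2FC column per contrast.
#' @param padj adjusted p-value recorded for every row (default 1e-4,
#'   i.e. "significant at any conventional alpha").
#' @return Named list of data.frames (`feature`, `log2fc`, `t`, `p`,
#'   `padj`), one per contrast column.
#' @export
lfc_table_as_results <- function(tab, padj = 1e-4) {
  id_col <- if ("mirna" %in% names(tab)) "mirna" else names(tab)[1]
  contrasts <- setdiff(names(tab), id_col)
  out <- lapply(contrasts, function(cn)
    data.frame(feature = tab[[id_col]], log2fc = tab[[cn]],
               t = NA_real_, p = padj, padj = padj,
               stringsAsFactors = FALSE))
  names(out) <- contrasts
  out
}

#' Run the integrative pipeline on simulated data
#'
#' Chains the full analysis on one synthetic dataset: quantile-spline
#' normalization of the Cp matrix, per-resistant-line differential
#' expression (Cp scale, sign following abundance), candidate selection at
#' `|log2FC| >= lfc_threshold`, replicate-mean summarization, negated
#' Cp-expression correlation over condition means, the predicted
#' functional-target inference gated by multi-tool support, and
#' planted-edge precision/recall against the ground truth.
#'
#' @param config a [sim_config()].
#' @param lfc_threshold candidate fold-change threshold (default 0.7).
#' @param r_threshold negated-correlation threshold (default -0.8).
#' @param min_support predictor-support gate (default 2).
#' @param normalize logical; apply [fit_qspline()] normalization before
#'   differential expression (default TRUE).
#' @return List: `sim`, `de` (per-contrast results), `candidates`,
#'   `targets` (functional target set), `precision`, `recall` against the
#'   planted edges, `predictions`.
#' @export
run_pipeline <- function(config = sim_config(), lfc_threshold = 0.7,
                         r_threshold = -0.8, min_support = 2L,
                         normalize = TRUE) {
  truth <- simulate_truth(config)
  sim <- simulate_expression(truth, config)
  predictions <- simulate_predictions(truth, config)

  cp <- sim$cp
  if (normalize) {
    model <- fit_qspline(cp)
    cp <- apply_normalization(cp, model)
  }
  reference <- sim$truth$conditions[1]
  resistant <- setdiff(sim$truth$conditions, reference)
  de <- lapply(resistant, function(cond)
    de_test(cp, sim$condition_map, c(cond, reference), type = "cp"))
  names(de) <- resistant

  candidates <- select_candidates(de, lfc_threshold)
  mirna_means <- condition_means(cp, sim$condition_map)
  gene_means <- condition_means(sim$expr, sim$condition_map)
  corr <- correlate(mirna_means[candidates, , drop = FALSE], gene_means)
  targets <- infer_functional_targets(corr, predictions,
                                      r_threshold = r_threshold,
                                      min_support = min_support)

  truth_key <- paste(truth$edges$mirna, truth$edges$gene)
  found_key <- paste(targets$mirna, targets$gene)
  tp <- sum(found_key %in% truth_key)
  precision <- if (length(found_key)) tp / length(found_key) else NA_real_
  recall <- if (length(truth_key)) tp / length(truth_key) else NA_real_

  list(sim = sim, de = de, candidates = candidates, targets = targets,
       precision = precision, recall = recall, predictions = predictions,
       corr = corr)
}
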