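#' Replicate means per condition
#'
#' Summarizes a feature x sample matrix to one value per (feature,
#' condition) by averaging detected replicates. A mean over fewer than
#' `min_detected` detected replicates is marked missing, and features
#' missing in any condition are flagged for exclusion from correlation.
#'
#' @param m feature x sample matrix (Cp or log2 expression).
#' @param condition_map named character vector (sample -> condition).
#' @param min_detected minimum detected replicates per condition mean
#'   (default 2, matching the missing-Cp convention).
#' @return Feature x condition matrix of means with attribute `complete`
#'   (logical: no missing condition mean).
#' @export
condition_means <- function(m, condition_map, min_detected = 2L) {
  condition_map <- check_condition_map(colnames(m), condition_map)
  conds <- unique(condition_map)
  for (cond in conds)
    if (!any(condition_map == cond))
      stop("condition with zero samples: ", cond, call. = FALSE)
  out <- sapply(conds, function(cond) {
    cols <- names(condition_map)[condition_map == cond]
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[rowSums(!is.na(sub)) < min_detected] <- NA_real_
    mu
  })
  rownames(out) <- rownames(m)
  attr(out, "complete") <- stats::complete.cases(out)
  out
}

#' Negated Pearson correlation of miRNA Cp vs gene expression
#'
#' For each (miRNA, gene) pair the Pearson correlation between the miRNA's
#' Cp condition means and the gene's expression condition means is computed
#' and *negated*: because Cp is inversely proportional to abundance, a
#' repressed target (abundance up, target down) gives a strongly *positive*
#' Cp-expression correlation, hence a strongly *negative* entry after
#' negation. Entries at or below the downstream threshold (default -0.8)
#' are the inverse-association evidence. Zero-variance profiles yield `NA`
#' entries (dropped downstream, tallied in attribute `n_undefined`).
#'
#' @param mirna_means miRNA x condition matrix of Cp means (candidates
#'   only), from [condition_means()].
#' @param gene_means gene x condition matrix of expression means.
#' @return miRNA x gene matrix of negated Pearson r with attributes
#'   `n_conditions` and `n_undefined`.
#' @export
correlate <- function(mirna_means, gene_means) {
  shared <- intersect(colnames(mirna_means), colnames(gene_means))
  if (length(shared) < 3)
    stop("need >= 3 shared conditions for correlation", call. = FALSE)
  mm <- mirna_means[, shared, drop = FALSE]
  gm <- gene_means[, shared, drop = FALSE]
  keep_m <- stats::complete.cases(mm)
  keep_g <- stats::complete.cases(gm)
  mm <- mm[keep_m, , drop = FALSE]
  gm <- gm[keep_g, , drop = FALSE]
  suppressWarnings(r <- -stats::cor(t(mm), t(gm)))
  # zero-variance rows/cols produce NaN; normalize to NA
  r[is.nan(r)] <- NA_real_
  attr(r, "n_conditions") <- length(shared)
  attr(r, "n_undefined") <- sum(is.na(r))
  r
}

#' Infer predicted functional miRNA targets
#'
#' A computationally predicted pair is called a *predicted functional
#' target* when its negated correlation is at or below `r_threshold`
#' (strong inverse association of abundance and expression) and at least
#' `min_support` distinct prediction tools back the pair. Both comparisons
#' are inclusive at the printed values (r <= -0.8, support >= 2).
#'
#' @param corr miRNA x gene negated-correlation matrix from [correlate()].
#' @param predictions data.frame of (mirna, gene, predictor) triples.
#' @param r_threshold inclusive negated-correlation threshold
#'   (default -0.8).
#' @param min_support inclusive minimum predictor support (default 2).
#' @return data.frame `mirna`, `gene`, `r`, `support`, sorted by miRNA id
#'   then ascending r (class `functional_targets`).
#' @export
infer_functional_targets <- function(corr, predictions, r_threshold = -0.8,
                                     min_support = 2L) {
  supp <- prediction_support(predictions)
  supp <- supp[supp$mirna %in% rownames(corr) & supp$gene %in% colnames(corr), ,
               drop = FALSE]
  if (!nrow(supp)) {
    out <- data.frame(mirna = character(), gene = character(), r = numeric(),
                      support = integer(), stringsAsFactors = FALSE)
    class(out) <- c("functional_targets", class(out))
    return(out)
  }
  r <- corr[cbind(supp$mirna, supp$gene)]
  keep <- !is.na(r) & r <= r_threshold & supp$support >= min_support
  out <- data.frame(mirna = supp$mirna[keep], gene = supp$gene[keep],
                    r = r[keep], support = supp$support[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("functional_targets", class(out))
  out
}

#' Fraction of DE genes accounted for by DE miRNA regulation
#'
#' A differentially expressed gene is *accounted for* when it is a
#' predicted functional target of at least one differentially expressed
#' miRNA. Returns that fraction together with the 2x2 contingency table
#' (DE vs not-DE) x (targeted vs not-targeted) over the supplied gene
#' universe, ready for [odds_ratio()].
#'
#' @param de_genes character vector of DE gene ids.
#' @param fts [infer_functional_targets()] result.
#' @param de_mirnas character vector of DE miRNA ids.
#' @param universe all genes considered (defaults to the union of `de_genes`
#'   and the targets in `fts`).
#' @return List `fraction` (NA when `de_genes` is empty), `table` (2x2
#'   matrix), `accounted` (the accounted-for DE genes).
#' @export
regulation_coverage <- function(de_genes, fts, de_mirnas,
                                universe = NULL) {
  targeted <- unique(fts$gene[fts$mirna %in% de_mirnas])
  if (is.null(universe)) universe <- union(de_genes, fts$gene)
  de_genes <- intersect(de_genes, universe)
  targeted <- intersect(targeted, universe)
  accounted <- intersect(de_genes, targeted)
  fraction <- if (length(de_genes)) length(accounted) / length(de_genes)
              else NA_real_
  tab <- matrix(c(
    length(accounted),                                   # DE & targeted
    length(setdiff(de_genes, targeted)),                 # DE & not targeted
    length(setdiff(targeted, de_genes)),                 # not DE & targeted
    length(setdiff(universe, union(de_genes, targeted))) # neither
  ), 2L, 2L, byrow = TRUE,
  dimnames = list(c("DE", "notDE"), c("targeted", "notTargeted")))
  list(fraction = fraction, table = tab, accounted = accounted)
}
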