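#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: order the m p-values increasingly, form
#' `p_(i) * m / i`, take the running minimum from the largest rank down,
#' and cap at 1. The output is non-decreasing in raw-p rank and never below
#' the raw p-value.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
    out[ok] <- adj
  }
  out
}

# Exact null tail of the moderated t given a (near-)constant shrinkage
# target: T = Z / sqrt(w0 + w1*V) with V ~ chisq(df)/df, integrated
# numerically over V at midpoint nodes. Referring T to a t distribution
# with d0 + df df (as if the target were an independent chi-square prior)
# is measurably conservative here because the across-feature mean variance
# has negligible spread.
mod_t_pvalue <- function(tstat, df, d0, nodes = 401L) {
  p <- rep(NA_real_, length(tstat))
  u <- (seq_len(nodes) - 0.5) / nodes
  for (dfi in unique(df[!is.na(tstat)])) {
    idx <- which(df == dfi & !is.na(tstat))
    w0 <- d0 / (d0 + dfi)
    w1 <- dfi / (d0 + dfi)
    scl <- sqrt(w0 + w1 * stats::qchisq(u, dfi) / dfi)
    p[idx] <- vapply(tstat[idx], function(ti)
      mean(2 * stats::pnorm(-abs(ti) * scl)), numeric(1))
  }
  p
}

# moderated two-sample t on rows of a matrix: per-feature pooled variance
# shrunk toward the across-feature mean variance with prior weight d0
# (pseudo-replicates); returns delta = mean(group1) - mean(group2)
moderated_t_rows <- function(m, cols1, cols2, d0 = 2) {
  x1 <- m[, cols1, drop = FALSE]
  x2 <- m[, cols2, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  testable <- n1 >= 2 & n2 >= 2
  mu1 <- rowMeans(x1, na.rm = TRUE)
  mu2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- apply(x1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1L, stats::var, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  s2bar <- mean(s2[testable])
  s2mod <- (d0 * s2bar + df * s2) / (d0 + df)
  delta <- mu1 - mu2
  tstat <- delta / sqrt(s2mod * (1 / n1 + 1 / n2))
  tstat[!testable] <- NA_real_
  pval <- mod_t_pvalue(tstat, df, d0)
  delta[!testable] <- NA_real_
  tstat[!testable] <- NA_real_
  pval[!testable] <- NA_real_
  data.frame(feature = rownames(m), log2fc = unname(delta),
             t = unname(tstat), p = unname(pval), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential expression between two conditions
#'
#' Per feature, a two-sample t-test on the log2 (or Cp) scale with the
#' pooled variance moderated toward the across-feature mean variance
#' (`d0` pseudo-replicates of prior weight); p-values come from the exact
#' null of that statistic (normal over the square root of a shrunk
#' chi-square, integrated numerically) and are BH-adjusted across
#' features. For Cp input the mean difference is negated so a
#' positive log2 fold change always means the miRNA is *up* in the
#' resistant condition (lower Cp = higher abundance). Features with fewer
#' than two detected replicates on either side are reported untested
#' (`NA`).
#'
#' @param m feature x sample matrix (log2 expression, or Cp when
#'   `type = "cp"`).
#' @param condition_map named character vector (sample -> condition).
#' @param contrast length-2 character vector `c(resistant, reference)`.
#' @param type `"expr"` (mean difference as-is) or `"cp"` (negated).
#' @param d0 prior weight of the variance moderation (default 2).
#' @return data.frame `feature`, `log2fc`, `t`, `p`, `padj`.
#' @export
de_test <- function(m, condition_map, contrast, type = c("expr", "cp"),
                    d0 = 2) {
  type <- match.arg(type)
  condition_map <- check_condition_map(colnames(m), condition_map)
  if (!all(contrast %in% condition_map))
    stop("contrast condition(s) absent from condition map: ",
         paste(setdiff(contrast, condition_map), collapse = ", "),
         call. = FALSE)
  cols1 <- names(condition_map)[condition_map == contrast[1]]
  cols2 <- names(condition_map)[condition_map == contrast[2]]
  if (length(cols1) < 2 || length(cols2) < 2)
    stop("need >= 2 replicates on each side of the contrast", call. = FALSE)
  res <- moderated_t_rows(m, cols1, cols2, d0 = d0)
  if (type == "cp") {
    res$log2fc <- -res$log2fc
    res$t <- -res$t
  }
  res$padj <- bh_adjust(res$p)
  res
}

#' Differential expression on read counts
#'
#' Applies the moderated t machinery to `log2(normalized count + 0.5)`;
#' the log2 fold change is the difference of group means on that scale.
#' Features with zero counts in every sample are reported untested.
#'
#' @param counts feature x sample count matrix.
#' @param factors per-sample size factors (see [size_factors()]).
#' @inheritParams de_test
#' @return data.frame `feature`, `log2fc`, `t`, `p`, `padj`.
#' @export
de_counts <- function(counts, factors, condition_map, contrast, d0 = 2) {
  norm <- normalize_counts(counts, factors)
  logm <- log2(norm + 0.5)
  all_zero <- rowSums(counts) == 0
  logm[all_zero, ] <- NA_real_
  de_test(logm, condition_map, contrast, type = "expr", d0 = d0)
}

#' Cross-contrast sign-consistency signature
#'
#' The common resistance-associated signature: features significant
#' (adjusted p < `alpha`) in *all* contrasts with the *same* sign of log2
#' fold change throughout. Features mixed in sign, or missing significance
#' in any contrast, are excluded.
#'
#' @param results named list of >= 3 [de_test()] results over the same
#'   feature space (one per resistant cell line).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return List of class `consistent_signature`: `up`, `down` (feature
#'   ids), `lfc` (member x contrast log2 fold-change matrix).
#' @export
consistent_signature <- function(results, alpha = 0.05) {
  if (length(results) < 3)
    stop("need >= 3 contrasts for the consistency signature", call. = FALSE)
  features <- results[[1]]$feature
  for (r in results[-1])
    if (!identical(sort(r$feature), sort(features)))
      stop("contrasts cover different feature spaces", call. = FALSE)
  lfc <- vapply(results, function(r) r$log2fc[match(features, r$feature)],
                numeric(length(features)))
  padj <- vapply(results, function(r) r$padj[match(features, r$feature)],
                 numeric(length(features)))
  if (is.null(dim(lfc))) {  # single-feature edge case
    lfc <- matrix(lfc, nrow = 1)
    padj <- matrix(padj, nrow = 1)
  }
  rownames(lfc) <- rownames(padj) <- features
  sig <- !is.na(padj) & padj < alpha
  all_sig <- rowSums(sig) == ncol(sig)
  up <- all_sig & rowSums(lfc > 0, na.rm = TRUE) == ncol(lfc)
  down <- all_sig & rowSums(lfc < 0, na.rm = TRUE) == ncol(lfc)
  keep <- up | down
  structure(list(up = features[up], down = features[down],
                 lfc = lfc[keep, , drop = FALSE]),
            class = "consistent_signature")
}

#' Select candidate features by fold-change magnitude
#'
#' Features with `|log2FC| >= lfc_threshold` in at least one contrast,
#' ignoring p-values entirely (the candidate pool for the
#' inverse-correlation integration).
#'
#' @param results list of [de_test()] results (>= 1 contrast).
#' @param lfc_threshold inclusive magnitude threshold (default 0.7).
#' @return Character vector of feature ids (order of first appearance).
#' @export
select_candidates <- function(results, lfc_threshold = 0.7) {
  if (!length(results)) stop("need >= 1 contrast", call. = FALSE)
  hits <- character()
  for (r in results) {
    sel <- !is.na(r$log2fc) & abs(r$log2fc) >= lfc_threshold
    hits <- c(hits, r$feature[sel])
  }
  unique(hits)
}
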