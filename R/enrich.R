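#' Signed Wilcoxon rank-sum enrichment of a target set
#'
#' Two-sided rank-sum test comparing the fold changes of a miRNA's
#' predicted functional targets against the background of non-targeted
#' genes (which includes predicted-but-not-functional targets). When both
#' sides have at most `exact_max` observations and the data are tie-free
#' the exact null distribution of the Mann-Whitney U statistic is used
#' (two-sided by tail doubling); otherwise the normal approximation with
#' mid-rank tie correction and continuity correction applies. The signed
#' log10 p is `-log10(p)` carrying a *negative* sign when the targets rank
#' lower (smaller fold changes, i.e. more downregulated) than the
#' background, a *positive* sign when they rank higher, and 0 at exact
#' balance.
#'
#' @param fold_changes named numeric vector of per-gene log2 fold changes.
#' @param targets gene ids of the target set.
#' @param background gene ids of the background set (disjoint from
#'   `targets`).
#' @param exact_max per-side size limit for the exact null (default 10).
#' @return List: `p`, `signed_log10_p`, `sign` (-1/0/1), `U`,
#'   `n_targets`, `n_background`, `exact`.
#' @export
wilcoxon_enrichment <- function(fold_changes, targets, background,
                                exact_max = 10L) {
  targets <- intersect(targets, names(fold_changes))
  background <- intersect(background, names(fold_changes))
  if (length(intersect(targets, background)))
    stop("targets and background must be disjoint", call. = FALSE)
  if (!length(targets) || !length(background))
    stop("both target and background sides must be non-empty", call. = FALSE)
  x <- fold_changes[targets]
  y <- fold_changes[background]
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(c(x, y)))
  exact <- n1 <= exact_max && n2 <= exact_max && !ties
  if (exact) {
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    nt <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    # continuity correction toward the null mean
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  s <- sign(u - mu)
  list(p = p, signed_log10_p = s * -log10(p), sign = s, U = unname(u),
       n_targets = n1, n_background = n2, exact = exact)
}

#' Per-miRNA target enrichment across a functional target set
#'
#' Runs [wilcoxon_enrichment()] for every miRNA with at least one
#' functional target, against the background of all other genes in
#' `fold_changes`, and adjusts p-values across miRNAs by
#' Benjamini-Hochberg. miRNAs with fewer than 3 targets are flagged
#' low-power.
#'
#' @param fold_changes named numeric vector of per-gene log2 fold changes
#'   (one contrast).
#' @param fts [infer_functional_targets()] result.
#' @return data.frame `mirna`, `n_targets`, `p`, `padj`,
#'   `signed_log10_p`, `low_power`.
#' @export
enrichment_suite <- function(fold_changes, fts) {
  mirnas <- unique(fts$mirna)
  mirnas <- mirnas[vapply(mirnas, function(m)
    length(intersect(fts$gene[fts$mirna == m], names(fold_changes))) > 0,
    logical(1))]
  if (!length(mirnas))
    stop("no miRNA with >= 1 functional target in the fold-change vector",
         call. = FALSE)
  rows <- lapply(mirnas, function(m) {
    tg <- intersect(unique(fts$gene[fts$mirna == m]), names(fold_changes))
    bg <- setdiff(names(fold_changes), tg)
    res <- wilcoxon_enrichment(fold_changes, tg, bg)
    data.frame(mirna = m, n_targets = res$n_targets, p = res$p,
               signed_log10_p = res$signed_log10_p,
               low_power = res$n_targets < 3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  # recompute the signed value on the raw p (sign is a property of the raw
  # test); keep columns in a stable order
  out[, c("mirna", "n_targets", "p", "padj", "signed_log10_p", "low_power")]
}

#' Odds ratio and Fisher exact p for a 2x2 table
#'
#' Odds ratio `(a*d)/(b*c)` with the Haldane correction (0.5 added to every
#' cell) when any cell is zero; two-sided Fisher exact p computed by
#' doubling the smaller hypergeometric tail (capped at 1).
#'
#' @param tab 2x2 matrix of non-negative counts
#'   (rows: DE / not-DE; columns: targeted / not-targeted).
#' @return List `or`, `p`.
#' @export
odds_ratio <- function(tab) {
  if (!all(dim(tab) == c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("all-zero table", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  # hypergeometric: X = top-left cell, margins fixed
  r1 <- a + b; c1 <- a + c_; n <- sum(tab)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  supp <- lo:hi
  dens <- stats::dhyper(supp, c1, n - c1, r1)
  p_le <- sum(dens[supp <= a])
  p_ge <- sum(dens[supp >= a])
  p <- min(1, 2 * min(p_le, p_ge))
  list(or = or, p = p)
}

#' Hypergeometric over-representation test
#'
#' One-sided hypergeometric p for over-representation of `hits` in each
#' gene set relative to `universe`, BH-adjusted across sets. A generic
#' over-representation utility for user-supplied pathway collections.
#'
#' @param hits character vector of hit gene ids (must be within `universe`).
#' @param universe character vector of all gene ids considered.
#' @param gene_sets named list of character vectors (gene sets; intersected
#'   with `universe`).
#' @return data.frame `set`, `n_set`, `n_overlap`, `p`, `padj`.
#' @export
ora_hypergeometric <- function(hits, universe, gene_sets) {
  hits <- unique(hits)
  universe <- unique(universe)
  if (length(setdiff(hits, universe)))
    stop("hit set must be a subset of the universe", call. = FALSE)
  n <- length(universe)
  k <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(hits, gs))
    p <- if (k == 0) 1 else
      stats::phyper(ov - 1, length(gs), n - length(gs), k,
                    lower.tail = FALSE)
    data.frame(set = nm, n_set = length(gs), n_overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}
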