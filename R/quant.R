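#' Trim small-RNA reads (3' adapter and quality)
#'
#' If `adapter` is given, each read is scanned for the leftmost position at
#' which its suffix equals a prefix of the adapter (minimum overlap
#' `min_overlap`); everything from that position on is removed. Low-quality
#' 3' ends are then trimmed with the running-sum algorithm: the kept prefix
#' ends at the position maximizing the suffix sum of `(cutoff - q)`, i.e.
#' trailing bases are dropped while they are, on balance, below the cutoff.
#' Reads shorter than `min_len` after trimming are dropped (counted, not
#' errors).
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`
#'   (Phred+33 strings), as returned by [read_fastq()] or
#'   [simulate_reads()].
#' @param adapter optional 3' adapter sequence.
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param min_len minimum read length after trimming (default 15 nt).
#' @param min_overlap minimum read/adapter overlap for adapter removal.
#' @return List with `reads` (the surviving trimmed reads, same columns)
#'   and `stats` (named integer vector: `input`, `adapter_trimmed`,
#'   `quality_trimmed`, `dropped`, `kept`).
#' @export
trim_reads <- function(reads, adapter = NULL, quality_cutoff = 20L,
                       min_len = 15L, min_overlap = 5L) {
  seqs <- reads$sequence
  quals <- reads$quality
  n <- length(seqs)
  n_adapter <- 0L
  n_quality <- 0L

  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- toupper(chartr("U", "T", adapter))
    for (i in seq_len(n)) {
      s <- seqs[i]
      L <- nchar(s)
      # leftmost start where the read suffix matches an adapter prefix
      hit <- 0L
      for (p in seq_len(max(0L, L - min_overlap + 1L))) {
        k <- L - p + 1L
        if (substr(s, p, L) == substr(adapter, 1L, k)) { hit <- p; break }
      }
      if (hit > 0L) {
        seqs[i] <- substr(s, 1L, hit - 1L)
        quals[i] <- substr(quals[i], 1L, hit - 1L)
        n_adapter <- n_adapter + 1L
      }
    }
  }

  for (i in seq_len(n)) {
    L <- nchar(seqs[i])
    if (L == 0L) next
    q <- utf8ToInt(quals[i]) - 33L
    # running sum from the 3' end; cut where it is maximal and positive
    s <- cumsum(rev(quality_cutoff - q))
    best <- which.max(s)
    if (s[best] > 0) {
      keep <- L - best
      seqs[i] <- substr(seqs[i], 1L, keep)
      quals[i] <- substr(quals[i], 1L, keep)
      n_quality <- n_quality + 1L
    }
  }

  len <- nchar(seqs)
  keep <- len >= min_len
  out <- data.frame(id = reads$id[keep], sequence = seqs[keep],
                    quality = quals[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(reads = out,
       stats = c(input = n, adapter_trimmed = n_adapter,
                 quality_trimmed = n_quality, dropped = sum(!keep),
                 kept = sum(keep)))
}

#' Collapse reads to unique sequences with copy numbers
#'
#' @param sequences character vector of (trimmed) read sequences.
#' @return data.frame `sequence`, `copies`, sorted by decreasing copies then
#'   sequence; `sum(copies)` equals the number of input reads.
#' @export
dedupe_reads <- function(sequences) {
  if (!length(sequences))
    return(data.frame(sequence = character(), copies = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), copies = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$copies, out$sequence), , drop = FALSE]
}

#' Collapse a reference into identical-sequence groups
#'
#' miRNA paralogs can share one mature sequence; a literal per-id
#' multi-mapper discard would zero out such families. Identical sequences
#' are therefore collapsed into groups before matching, and a read hitting
#' one group counts once for it.
#'
#' @param reference named character vector (miRNA id -> mature sequence);
#'   `U` is normalized to `T`.
#' @return data.frame `group`, `sequence`, `members` (ids joined by `,`);
#'   the group id is the first member id.
#' @export
sequence_groups <- function(reference) {
  seqs <- toupper(chartr("U", "T", reference))
  split_ids <- split(names(seqs), unname(seqs))
  data.frame(group = vapply(split_ids, `[[`, "", 1L),
             sequence = names(split_ids),
             members = vapply(split_ids, paste, "", collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Match unique reads exactly to reference sequence groups
#'
#' A read is assigned to a group iff the read is an exact substring of the
#' group's sequence or vice versa (no mismatches or gaps). Reads matching
#' more than one distinct group are discarded as multi-mapped; unmatched
#' reads are tallied. Matching is order-independent: shuffling reads or
#' reference rows leaves the counts unchanged.
#'
#' @param unique_reads data.frame `sequence`, `copies` from
#'   [dedupe_reads()].
#' @param groups data.frame from [sequence_groups()].
#' @return List with `counts` (named integer vector per group),
#'   `multi_mapped`, `unmatched` (read copies in each bin). Conservation:
#'   `sum(counts) + multi_mapped + unmatched == sum(unique_reads$copies)`.
#' @export
match_reads <- function(unique_reads, groups) {
  counts <- stats::setNames(integer(nrow(groups)), groups$group)
  multi <- 0L
  unmatched <- 0L
  for (i in seq_len(nrow(unique_reads))) {
    rs <- unique_reads$sequence[i]
    cp <- unique_reads$copies[i]
    hits <- which(vapply(groups$sequence, function(gs)
      if (nchar(rs) <= nchar(gs)) grepl(rs, gs, fixed = TRUE)
      else grepl(gs, rs, fixed = TRUE), logical(1)))
    if (length(hits) == 1L) counts[hits] <- counts[hits] + cp
    else if (length(hits) > 1L) multi <- multi + cp
    else unmatched <- unmatched + cp
  }
  list(counts = counts, multi_mapped = multi, unmatched = unmatched)
}

#' Quantify one FASTQ sample against a mature miRNA reference
#'
#' Chains [trim_reads()], [dedupe_reads()], [sequence_groups()] and
#' [match_reads()] and reports per-stage tallies.
#'
#' @param reads data.frame (`id`, `sequence`, `quality`).
#' @param reference named character vector (id -> mature sequence).
#' @inheritParams trim_reads
#' @return List with `counts` (named integer per sequence group) and `qc`
#'   (named numeric: input, kept, dropped, assigned, multi_mapped,
#'   unmatched).
#' @export
quantify_sample <- function(reads, reference, adapter = NULL,
                            quality_cutoff = 20L, min_len = 15L) {
  tr <- trim_reads(reads, adapter = adapter, quality_cutoff = quality_cutoff,
                   min_len = min_len)
  uq <- dedupe_reads(tr$reads$sequence)
  grp <- sequence_groups(reference)
  m <- match_reads(uq, grp)
  list(counts = m$counts,
       qc = c(tr$stats[c("input", "kept", "dropped")],
              assigned = sum(m$counts), multi_mapped = m$multi_mapped,
              unmatched = m$unmatched))
}

#' Median-of-ratios size factors
#'
#' The reference is the per-feature geometric mean across samples (features
#' with any zero count are excluded); each sample's factor is the median
#' over features of its counts divided by the reference.
#'
#' @param counts feature x sample count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature with positive counts in every sample", call. = FALSE)
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  apply(counts[pos, , drop = FALSE], 2L, function(col)
    stats::median(col / ref))
}

#' @rdname size_factors
#' @param factors per-sample size factors.
#' @return `normalize_counts`: matrix of counts divided by their sample's
#'   factor (no longer integer).
#' @export
normalize_counts <- function(counts, factors) {
  sweep(counts, 2L, factors, "/")
}
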