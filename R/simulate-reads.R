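#' Simulate a mature miRNA reference
#'
#' Draws one random mature sequence (20-23 nt over ACGT) per miRNA in the
#' truth. Sequences are unique by construction (resampled on collision), so
#' by default every reference entry forms its own sequence group; pass a
#' custom reference to [simulate_reads()] to exercise identical-sequence
#' families.
#'
#' @param truth a [simulate_truth()] result.
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @return Named character vector, miRNA id -> mature sequence.
#' @export
simulate_reference <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "regulatory_truth"))
  with_seed(config$seed + 3L, {
    n <- length(truth$mirna_ids)
    seqs <- character(n)
    seen <- character()
    for (i in seq_len(n)) {
      repeat {
        len <- sample(20:23, 1L)
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        if (!(s %in% seen)) break
      }
      seqs[i] <- s
      seen <- c(seen, s)
    }
    names(seqs) <- truth$mirna_ids
    seqs
  })
}

#' Simulate small-RNA sequencing reads
#'
#' Draws reads multinomially across miRNAs in proportion to their (linear)
#' abundance. Each read is the mature sequence, optionally extended at the
#' 3' end with the library adapter and truncated to the sequenced read
#' length; base qualities are high over the insert and decay over the
#' adapter-derived 3' tail, emulating the quality drop that 3' quality
#' trimming must remove.
#'
#' @param truth a [simulate_truth()] result.
#' @param reference named character vector (miRNA id -> mature sequence,
#'   18-30 nt over ACGTU); see [simulate_reference()].
#' @param config a [sim_config()]; `n_reads`, `read_length` and `adapter`
#'   are taken from it.
#' @param abundance optional named linear-scale abundance vector overriding
#'   `2^baseline_log2` from the truth.
#' @return List with `reads` (data.frame `id`, `sequence`, `quality`;
#'   qualities as Phred+33 strings) and `counts` (named integer vector, the
#'   per-miRNA ground-truth draw).
#' @export
simulate_reads <- function(truth, reference, config = truth$config,
                           abundance = NULL) {
  stopifnot(inherits(truth, "regulatory_truth"))
  if (length(reference) == 0) stop("empty reference", call. = FALSE)
  reference <- toupper(chartr("U", "T", reference))
  lens <- nchar(reference)
  if (any(lens < 18 | lens > 30))
    stop("reference sequences must be 18-30 nt", call. = FALSE)
  if (any(grepl("[^ACGT]", reference)))
    stop("reference sequences must be over {A,C,G,T,U}", call. = FALSE)
  ids <- names(reference)
  if (is.null(abundance))
    abundance <- 2^truth$baseline_log2[ids]
  abundance <- abundance[ids]
  if (all(abundance == 0)) stop("all abundances zero", call. = FALSE)

  with_seed(config$seed + 4L, {
    counts <- as.integer(stats::rmultinom(1L, config$n_reads,
                                          abundance / sum(abundance)))
    names(counts) <- ids
    origin <- rep(ids, counts)
    seqs <- reference[origin]
    n <- length(seqs)
    quals <- character(n)
    if (!is.null(config$adapter)) {
      full <- paste0(seqs, config$adapter)
      insert_len <- nchar(seqs)
      seqs <- substr(full, 1L, config$read_length)
      for (i in seq_len(n)) {
        L <- nchar(seqs[i])
        q <- rep(38L, L)
        tail_len <- max(0L, L - insert_len[i])
        if (tail_len > 0) {
          # linear decay from Q30 down to Q2 over the adapter tail
          q[(insert_len[i] + 1L):L] <-
            pmax(2L, as.integer(round(seq(30, 2, length.out = tail_len))))
        }
        quals[i] <- intToUtf8(q + 33L)
      }
    } else {
      for (i in seq_len(n)) quals[i] <- intToUtf8(rep(38L + 33L, nchar(seqs[i])))
    }
    reads <- data.frame(id = sprintf("read_%06d", seq_len(n)),
                        sequence = unname(seqs), quality = quals,
                        stringsAsFactors = FALSE)
    # shuffle so read order carries no information about origin
    perm <- sample.int(n)
    list(reads = reads[perm, , drop = FALSE], counts = counts)
  })
}

#' Simulate patient cohorts with logistic recurrence labels
#'
#' Generates per-cohort sample x miRNA log2 expression matrices for the
#' marker miRNAs plus background miRNAs, and draws binary recurrence labels
#' from a logistic model on the standardized marker expressions with
#' cohort-specific intercepts. With the default coefficients two markers
#' carry opposite-signed effects and two are null, so multi-marker
#' classifiers can outperform single markers downstream.
#'
#' @param config a [sim_config()].
#' @param n_background number of additional null miRNAs per cohort.
#' @return List of cohorts, each of class `cohort_dataset`: list with `id`,
#'   `x` (sample x miRNA log2 matrix) and `label` (integer 0/1).
#' @export
simulate_cohorts <- function(config = sim_config(), n_background = 6) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 5L, {
    mirnas <- c(config$markers,
                sprintf("miR-bg-%02d", seq_len(n_background)))
    out <- vector("list", length(config$cohort_sizes))
    for (k in seq_along(config$cohort_sizes)) {
      n <- config$cohort_sizes[k]
      x <- matrix(stats::rnorm(n * length(mirnas), mean = 8, sd = 1),
                  n, length(mirnas),
                  dimnames = list(sprintf("cohort%d_s%03d", k, seq_len(n)),
                                  mirnas))
      eta <- config$cohort_intercepts[k] +
        (x[, config$markers, drop = FALSE] - 8) %*% config$marker_beta
      label <- stats::rbinom(n, 1L, stats::plogis(drop(eta)))
      out[[k]] <- structure(list(id = paste0("cohort", k), x = x,
                                 label = as.integer(label)),
                            class = "cohort_dataset")
    }
    out
  })
}
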