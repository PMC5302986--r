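#' Read a feature x sample matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and feature
#' ids in the first column. `kind` selects the invariants enforced:
#' `"cp"` allows missing values (the `NA` sentinel, an undetected assay)
#' and requires values in (0, 45]; `"expr"` requires finite values;
#' `"count"` requires non-negative integers.
#'
#' @param path file path.
#' @param kind one of `"cp"`, `"expr"`, `"count"`.
#' @return Numeric (or integer, for counts) matrix with feature row names
#'   and sample column names.
#' @export
read_matrix <- function(path, kind = c("cp", "expr", "count")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  if (ncol(df) < 2) stop("matrix file needs a feature column and >= 1 sample",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  bad_col <- !vapply(vals, is.numeric, logical(1))
  if (any(bad_col))
    stop("non-numeric values in column(s): ",
         paste(names(vals)[bad_col], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  check_matrix(m, kind)
  if (kind == "count") storage.mode(m) <- "integer"
  m
}

check_matrix <- function(m, kind) {
  switch(kind,
    cp = {
      v <- m[!is.na(m)]
      if (any(v <= 0 | v > 45))
        stop("Cp values must lie in (0, 45] or be missing", call. = FALSE)
    },
    expr = if (any(!is.finite(m)))
      stop("expression matrix must be finite", call. = FALSE),
    count = {
      if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
        stop("count matrix must contain non-negative integers", call. = FALSE)
    })
  invisible(m)
}

#' Write a feature x sample matrix to TSV
#'
#' Deterministic writer: row and column order of the input are preserved.
#' Missing values are written as the `NA` sentinel.
#'
#' @param m matrix with row and column names.
#' @param path output path.
#' @param feature_col name for the first (feature id) column.
#' @export
write_matrix <- function(m, path, feature_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-to-condition map
#'
#' Two-column TSV (`sample`, `condition`).
#'
#' @param path file path.
#' @return Named character vector (sample -> condition).
#' @export
read_condition_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop("condition map needs 'sample' and 'condition' columns", call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in condition map", call. = FALSE)
  stats::setNames(df$condition, df$sample)
}

#' @rdname read_condition_map
#' @param condition_map named character vector (sample -> condition).
#' @export
write_condition_map <- function(condition_map, path) {
  utils::write.table(
    data.frame(sample = names(condition_map),
               condition = unname(condition_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a target-prediction table
#'
#' TSV with columns `mirna`, `gene`, `predictor`; duplicate triples are
#' rejected. Per-pair support counts are derived with [prediction_support()].
#'
#' @param path file path.
#' @return data.frame with columns `mirna`, `gene`, `predictor`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "predictor")
  if (!all(need %in% names(df)))
    stop("prediction table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  if (anyDuplicated(df))
    stop("duplicate (mirna, gene, predictor) triples", call. = FALSE)
  df
}

#' @rdname read_predictions
#' @param predictions data.frame of (mirna, gene, predictor) triples.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-pair predictor support counts
#'
#' @param predictions data.frame of (mirna, gene, predictor) triples.
#' @return data.frame `mirna`, `gene`, `support` (number of distinct
#'   predictors backing the pair).
#' @export
prediction_support <- function(predictions) {
  key <- paste(predictions$mirna, predictions$gene, sep = "\r")
  tab <- tapply(predictions$predictor, key, function(p) length(unique(p)))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(mirna = vapply(parts, `[[`, "", 1L),
             gene = vapply(parts, `[[`, "", 2L),
             support = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a FASTA reference of mature miRNA sequences
#'
#' Uses Biostrings; `U` is normalized to `T` and ids are truncated at the
#' first whitespace and required to be unique.
#'
#' @param path FASTA file.
#' @return Named character vector, id -> sequence (ACGT alphabet).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(chartr("U", "T", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids after whitespace truncation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  stats::setNames(unname(seqs), ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' Uses Biostrings. Malformed or truncated records raise an error.
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`
#'   (quality kept as a Phred+33 string; see [phred_scores()]).
#' @export
read_fastq <- function(path) {
  # structural validation first: Biostrings tolerates some truncations
  # and the error contract wants the offending line reported
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
  first <- seq(1L, length(lines), by = 4L)
  bad_hdr <- first[!startsWith(lines[first], "@")]
  if (length(bad_hdr))
    stop("malformed FASTQ '", path, "': missing '@' header at line ",
         bad_hdr[1], call. = FALSE)
  bad_sep <- first[!startsWith(lines[first + 2L], "+")]
  if (length(bad_sep))
    stop("malformed FASTQ '", path, "': missing '+' separator at line ",
         bad_sep[1] + 2L, call. = FALSE)
  bad_len <- first[nchar(lines[first + 1L]) != nchar(lines[first + 3L])]
  if (length(bad_len))
    stop("malformed FASTQ '", path, "': sequence/quality length mismatch ",
         "at line ", bad_len[1] + 1L, call. = FALSE)
  # suppress the harmless "metadata columns dropped" notice Biostrings
  # emits while assembling the quality-scaled set
  set <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"))
  suppressWarnings(data.frame(
    id = sub("\\s.*$", "", names(set)),
    sequence = as.character(set),
    quality = as.character(Biostrings::quality(set)),
    row.names = NULL, stringsAsFactors = FALSE))
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality character vector of Phred+33 strings.
#' @return List of integer vectors.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Read melting-curve traces from long-format TSV
#'
#' Columns `assay`, `temperature`, `fluorescence`; one row per grid point.
#'
#' @param path file path.
#' @return Named list of data.frames (`temperature`, `fluorescence`),
#'   one per assay, sorted by temperature.
#' @export
read_melt_curves <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("assay", "temperature", "fluorescence")
  if (!all(need %in% names(df)))
    stop("melt curve file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df[, c("temperature", "fluorescence")], df$assay),
         function(d) d[order(d$temperature), , drop = FALSE])
}

#' Read / write patient cohort tables
#'
#' TSV with columns `sample`, `cohort`, `label` and one column per miRNA.
#'
#' @param path file path.
#' @return List of `cohort_dataset` objects (see [simulate_cohorts()]).
#' @export
read_cohorts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "cohort", "label")
  if (!all(need %in% names(df)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$label %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  mir_cols <- setdiff(names(df), need)
  lapply(split(df, df$cohort), function(d) {
    x <- as.matrix(d[, mir_cols, drop = FALSE])
    rownames(x) <- d$sample
    structure(list(id = d$cohort[1], x = x, label = as.integer(d$label)),
              class = "cohort_dataset")
  })
}

#' @rdname read_cohorts
#' @param cohorts list of `cohort_dataset` objects.
#' @export
write_cohorts <- function(cohorts, path) {
  rows <- lapply(cohorts, function(co)
    data.frame(sample = rownames(co$x), cohort = co$id, label = co$label,
               co$x, check.names = FALSE, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a regulatory truth to JSON
#'
#' @param truth a [simulate_truth()] result.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(mirna_ids = truth$mirna_ids, gene_ids = truth$gene_ids,
         edges = truth$edges, conditions = truth$conditions,
         shifts = as.data.frame(truth$shifts),
         baseline_log2 = as.list(truth$baseline_log2)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
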