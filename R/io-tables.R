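#' Write / read a count matrix as TSV
#'
#' `write_tsv_matrix()` writes the counts (header row = sample ids, first
#' column = `feature_id`) plus a sidecar `<path>.samples.tsv` with the
#' sample metadata; `read_tsv_matrix()` reads the pair back.  The round
#' trip is lossless.
#'
#' @param matrix A [count_matrix()].
#' @param path TSV path for the counts; metadata goes to
#'   `paste0(path, ".samples.tsv")`.
#' @return `write_tsv_matrix()` returns `path` invisibly;
#'   `read_tsv_matrix()` returns a [count_matrix()].
#' @export
write_tsv_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "count_matrix"))
  ids <- rownames(matrix$counts)
  if (is.null(ids)) ids <- character(nrow(matrix$counts))
  df <- data.frame(feature_id = ids, matrix$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(matrix$samples, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  side <- paste0(path, ".samples.tsv")
  if (!file.exists(side)) stop_("missing sample metadata sidecar: ", side)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (anyDuplicated(df$feature_id)) stop_("duplicate feature_ids in ", path)
  meta <- utils::read.table(side, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  ids <- df$feature_id
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop_("non-numeric counts in ", path)
  if (any(m < 0)) stop_("negative count in ", path)
  rownames(m) <- ids
  ord <- match(colnames(m), meta$sample_id)
  if (anyNA(ord)) stop_("sample metadata sidecar does not cover all samples")
  count_matrix(m, condition = meta$condition[ord],
               replicate = meta$replicate[ord])
}

#' Read an externally computed differential table
#'
#' Accepts TSV exports of differential testing results (e.g. DESeq2 result
#' tables) with columns `feature_id`, `lfc`, `pvalue`, `padj`,
#' `comparison`, as a drop-in replacement for [differential_standin()].
#'
#' @param path TSV path.
#' @return data.frame with those five columns; `comparison` labels are kept
#'   as read.
#' @export
read_diff_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("feature_id", "lfc", "pvalue", "padj", "comparison")
  if (!all(need %in% names(df)))
    stop_("differential table needs columns: ", paste(need, collapse = ", "))
  bad <- with(df, pvalue < 0 | pvalue > 1 | padj < 0 | padj > 1)
  if (any(bad, na.rm = TRUE)) stop_("p-values outside [0, 1]")
  df[, need]
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings for plain (optionally line-wrapped)
#' FASTA of peak sequences keyed by peak id.
#'
#' @param path File path.
#' @param sequences Named character vector of A/C/G/T/N sequences.
#' @param width Line width on output.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
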