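#' Count matrix with sample metadata
#'
#' Container for a features x samples matrix of nonnegative integer counts
#' (RNA-seq gene counts or ATAC-seq peak counts) together with per-sample
#' condition/replicate metadata.  Conditions must come from the closed
#' six-condition vocabulary ([explant_conditions()]).
#'
#' @param counts Integer matrix, features in rows, samples in columns.  Row
#'   and column names are required and must be unique; all values finite and
#'   `>= 0`.
#' @param condition Character vector, one condition label per column.
#' @param replicate Positive integer vector, one replicate index per column.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `samples` (data.frame with `sample_id`,
#'   `condition`, `replicate`).
#' @export
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, condition = c("IMD", "D0"), replicate = c(1, 1))
#' dim(cm)
count_matrix <- function(counts, condition, replicate) {
  if (!is.matrix(counts)) stop_("'counts' must be a matrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    stop_("'counts' must have feature ids as rownames")
  if (is.null(colnames(counts))) stop_("'counts' must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop_("duplicate feature_ids")
  if (anyDuplicated(colnames(counts))) stop_("duplicate sample_ids")
  if (any(!is.finite(counts))) stop_("counts must be finite")
  if (any(counts < 0)) stop_("counts must be nonnegative")
  if (any(counts != round(counts))) stop_("counts must be integers")
  storage.mode(counts) <- "integer"
  if (length(condition) != ncol(counts) || length(replicate) != ncol(counts))
    stop_("'condition' and 'replicate' must have one entry per sample")
  bad <- setdiff(unique(condition), explant_conditions())
  if (length(bad))
    stop_("unknown condition(s): ", paste(bad, collapse = ", "),
          " (allowed: ", paste(explant_conditions(), collapse = ", "), ")")
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop_("'replicate' must be positive integers")
  structure(
    list(counts = counts,
         samples = data.frame(sample_id = colnames(counts),
                              condition = as.character(condition),
                              replicate = replicate,
                              stringsAsFactors = FALSE)),
    class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(factor(x$samples$condition, levels = explant_conditions()))
  cat("samples per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

# Internal container for real-valued (normalized or gene-level) matrices;
# keeps the sample metadata attached to the values.
new_norm_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), nrow(samples) == ncol(values))
  structure(list(values = values, samples = samples), class = "norm_matrix")
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Column means within condition; returns features x conditions matrix with
# the condition labels (in vocabulary order) as colnames.
condition_means <- function(values, samples) {
  conds <- intersect(explant_conditions(), unique(samples$condition))
  out <- vapply(conds, function(cc) {
    j <- which(samples$condition == cc)
    if (length(j) == 1L) values[, j] else rowMeans(values[, j, drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(rownames(values), conds))
  rownames(out) <- rownames(values)
  out
}
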