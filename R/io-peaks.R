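#' Read peaks from BED or narrowPeak
#'
#' Reads peak intervals from a BED3+ or ENCODE 10-column narrowPeak file.
#' File coordinates are 0-based half-open; they are converted once, at this
#' parse boundary, to the package-internal 1-based inclusive convention
#' (`start_1 = start + 1`, `end` unchanged).  For narrowPeak the 10th column
#' (summit offset from the 0-based start) is kept; `-1` means "no summit"
#' and is stored as `NA`.
#'
#' @param path File path.
#' @param dialect `"BED"` or `"narrowPeak"`.
#' @return data.frame with columns `peak_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `summit_offset` (integer or `NA`) and `summit`
#'   (absolute 1-based summit position, `NA` when absent).  Records lacking
#'   a name column get ids `peak_1, peak_2, ...` in file order.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "BED")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  ncolmin <- if (dialect == "BED") 3L else 10L
  if (ncol(df) < ncolmin)
    stop_(dialect, " requires at least ", ncolmin, " columns, found ", ncol(df))
  bad <- which(df[[2L]] >= df[[3L]])
  if (length(bad))
    stop_("invalid interval (start >= end) in record ", bad[1L], ": ",
          paste(df[bad[1L], 1:3], collapse = "\t"))
  if (any(df[[2L]] < 0)) stop_("negative start coordinate")
  ids <- if (ncol(df) >= 4L && !all(df[[4L]] == ".")) as.character(df[[4L]])
         else paste0("peak_", seq_len(nrow(df)))
  summit_offset <- rep(NA_integer_, nrow(df))
  if (dialect == "narrowPeak") {
    so <- as.integer(df[[10L]])
    width <- df[[3L]] - df[[2L]]
    if (any(so >= width, na.rm = TRUE))
      stop_("summit offset >= peak width in record ",
            which(so >= width)[1L])
    summit_offset[so >= 0L] <- so[so >= 0L]
  }
  out <- data.frame(peak_id = ids, chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]] + 1L), end = as.integer(df[[3L]]),
                    summit_offset = summit_offset, stringsAsFactors = FALSE)
  out$summit <- ifelse(is.na(out$summit_offset), NA_integer_,
                       out$start + out$summit_offset)
  out
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_peaks()]: internal 1-based inclusive intervals are
#' written back as 0-based half-open narrowPeak records (summit offset `-1`
#' when absent).
#'
#' @param peaks data.frame as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  so <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t0\t-1\t-1\t%d",
                   peaks$chrom, peaks$start - 1L, peaks$end, peaks$peak_id, so)
  writeLines(lines, path)
  invisible(path)
}

#' Read position weight matrices from a JASPAR PFM file
#'
#' Parses the JASPAR 2016+ text format (`>ID NAME` header, one bracketed
#' count row per base A/C/G/T).  Counts are converted to per-column
#' probabilities after adding a pseudocount to every cell, so columns sum to
#' one and no cell is exactly zero.
#'
#' @param path File path.
#' @param pseudocount Added to each count cell before column normalization
#'   (default 0.5, avoiding infinite log-odds).
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1.  Default uniform.
#' @return List of `pwm` objects: each a list with `motif_id`, `name`,
#'   `matrix` (4 x L probability matrix, rows A/C/G/T) and `background`.
#' @export
read_jaspar <- function(path, pseudocount = 0.5,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!file.exists(path)) stop_("no such file: ", path)
  if (abs(sum(background) - 1) > 1e-9) stop_("background must sum to 1")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_("no '>' motif headers found")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (m in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[m]])
    parts <- strsplit(hdr, "\\s+")[[1L]]
    body <- lines[(starts[m] + 1L):(bounds[m + 1L] - 1L)]
    if (length(body) < 4L) stop_("motif ", parts[1L], ": expected 4 base rows")
    rows <- lapply(body[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L)
      stop_("motif ", parts[1L], ": count rows have unequal lengths")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0) || anyNA(counts)) stop_("motif ", parts[1L],
                                                ": invalid counts")
    prob <- counts + pseudocount
    prob <- sweep(prob, 2L, colSums(prob), "/")
    out[[m]] <- structure(
      list(motif_id = parts[1L],
           name = if (length(parts) > 1L) parts[2L] else parts[1L],
           matrix = prob, background = background),
      class = "pwm")
  }
  out
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d, consensus %s\n",
              x$motif_id, x$name, ncol(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The highest-probability base at each position.
#'
#' @param pwm A `pwm` object from [read_jaspar()].
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste0(rownames(pwm$matrix)[apply(pwm$matrix, 2L, which.max)], collapse = "")
}
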