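#' Scan sequences for PWM hits
#'
#' Log2-odds scanning of region sequences against a PWM: every window of
#' motif length on both strands is scored as
#' `sum(log2(p[base, i] / background[base]))`; `N` bases contribute zero
#' log-odds.  A window is a hit when its score reaches `score_fraction`
#' times the maximum attainable score of the motif.  Sequences shorter
#' than the motif simply yield no hits.
#'
#' @param sequences Named character vector of A/C/G/T/N sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param pwm A `pwm` object (see [read_jaspar()]).
#' @param score_fraction Hit threshold as a fraction of the maximum
#'   attainable score (default 0.8).
#' @return List with `hit` (named logical per sequence) and `positions`
#'   (data.frame `seq_id`, `start` — 1-based position of the window's
#'   leftmost base on the forward strand —, `strand`, `score`).
#' @export
scan_pwm <- function(sequences, pwm, score_fraction = 0.8) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences))) names(sequences) <- paste0("seq_", seq_along(sequences))
  lut <- log2(pwm$matrix / pwm$background)     # 4 x L
  lut <- rbind(lut, N = 0)                     # N row: zero contribution
  max_score <- sum(apply(lut[1:4, , drop = FALSE], 2L, max))
  thr <- score_fraction * max_score
  W <- ncol(pwm$matrix)
  bases <- c("A", "C", "G", "T", "N")

  score_codes <- function(code) {
    nw <- length(code) - W + 1L
    if (nw < 1L) return(numeric(0))
    s <- numeric(nw)
    for (i in seq_len(W)) s <- s + lut[cbind(code[i:(i + nw - 1L)], i)]
    s
  }
  pos <- list()
  hit <- stats::setNames(logical(length(sequences)), names(sequences))
  for (si in seq_along(sequences)) {
    chars <- strsplit(toupper(sequences[[si]]), "")[[1L]]
    code <- match(chars, bases)
    code[is.na(code)] <- 5L
    fwd <- score_codes(code)
    rc <- rev(ifelse(code == 5L, 5L, 5L - code))  # reverse complement codes
    rev_ <- score_codes(rc)
    n <- length(code)
    hf <- which(fwd >= thr)
    hr <- which(rev_ >= thr)
    if (length(hf) || length(hr)) {
      hit[si] <- TRUE
      pos[[length(pos) + 1L]] <- data.frame(
        seq_id = names(sequences)[si],
        start = c(hf, n - (hr + W - 1L) + 1L),
        strand = rep(c("+", "-"), c(length(hf), length(hr))),
        score = c(fwd[hf], rev_[hr]),
        stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(pos)) do.call(rbind, pos) else
    data.frame(seq_id = character(), start = integer(), strand = character(),
               score = numeric(), stringsAsFactors = FALSE)
  list(hit = hit, positions = positions,
       max_score = max_score, threshold = thr)
}

#' Bin regions by differential-accessibility log fold change
#'
#' Partitions regions of one comparison into an odd number of LFC bins:
#' the centre bin holds the non-differential zone `|lfc| < lfc_center`,
#' and the remaining regions on each side are split into
#' `(n_bins - 1) / 2` equal-count bins by LFC rank (sizes differ by at
#' most one; the most extreme fold changes sit in the outermost bins).
#'
#' @param dar_results Differential table for one comparison (columns
#'   `feature_id`, `lfc`).
#' @param n_bins Odd number of bins, `>= 3` (default 5).
#' @param lfc_center Half-width of the centre bin (default 1.5, the DAR
#'   threshold).
#' @return Object of class `lfc_bins`: list with `assignment` (named
#'   integer, region -> bin index `1..n_bins`, left to right) and `bins`
#'   (data.frame `bin`, `lo`, `hi`, `n`; half-open ranges `[lo, hi)`).
#' @export
bin_regions_by_lfc <- function(dar_results, n_bins = 5L, lfc_center = 1.5) {
  if (n_bins < 3L || n_bins %% 2L == 0L) stop_("n_bins must be odd and >= 3")
  lfc <- dar_results$lfc
  ids <- dar_results$feature_id
  side_bins <- (n_bins - 1L) %/% 2L
  centre <- side_bins + 1L
  assignment <- stats::setNames(rep(centre, length(lfc)), ids)

  split_side <- function(values, first_bin, ascending) {
    # equal-count bins by rank; ascending=TRUE maps most negative outward
    n <- length(values)
    if (!n) return(NULL)
    ord <- order(values, decreasing = !ascending)
    base <- n %/% side_bins; extra <- n %% side_bins
    sizes <- base + c(rep(1L, extra), rep(0L, side_bins - extra))
    rep(seq.int(first_bin, by = if (ascending) 1L else -1L,
                length.out = side_bins), sizes)[order(ord)]
  }
  left <- lfc <= -lfc_center
  right <- lfc >= lfc_center
  if (any(left)) assignment[left] <- split_side(lfc[left], 1L, TRUE)
  if (any(right)) assignment[right] <- split_side(lfc[right], n_bins, FALSE)
  if (!any(left)) message("no regions on the negative-LFC side")
  if (!any(right)) message("no regions on the positive-LFC side")

  bins <- data.frame(bin = seq_len(n_bins),
                     lo = NA_real_, hi = NA_real_,
                     n = as.vector(table(factor(assignment, seq_len(n_bins)))))
  for (b in seq_len(n_bins)) {
    v <- lfc[assignment == b]
    if (length(v)) { bins$lo[b] <- min(v); bins$hi[b] <- max(v) }
  }
  bins$lo[centre] <- -lfc_center; bins$hi[centre] <- lfc_center
  structure(list(assignment = assignment, bins = bins,
                 n_bins = as.integer(n_bins), centre = centre),
            class = "lfc_bins")
}

#' @export
print.lfc_bins <- function(x, ...) {
  cat(sprintf("lfc_bins: %d regions in %d bins (centre bin %d)\n",
              length(x$assignment), x$n_bins, x$centre))
  print(x$bins)
  invisible(x)
}

#' Per-bin motif enrichment
#'
#' One-sided hypergeometric over-representation of motif hits in each LFC
#' bin against all other bins: for a bin with `k` regions of which `q`
#' carry a hit, out of `N` regions with `m` hits in total,
#' `p = P(X >= q | N, m, k)`.  The log2 enrichment compares hit fractions
#' in the bin versus the rest with pseudo-fraction `eps = 1/N`.  A
#' (motif, bin) pair is significant when `p < p_cutoff` (default 5e-5).
#'
#' @param hits Named logical vector (regions, one motif) or a logical
#'   matrix regions x motifs.
#' @param bins An `lfc_bins` object covering the same regions.
#' @param p_cutoff Significance cutoff (default `5e-5`).
#' @return data.frame with `motif`, `bin`, `n_regions`, `hit_regions`,
#'   `log2_enrichment`, `p`, `significant`.
#' @export
bin_enrichment <- function(hits, bins, p_cutoff = 5e-5) {
  stopifnot(inherits(bins, "lfc_bins"))
  if (bins$n_bins < 2L || sum(bins$bins$n > 0L) < 2L)
    stop_("need at least two populated bins (no background otherwise)")
  if (!is.matrix(hits)) hits <- cbind(motif = hits)
  regions <- names(bins$assignment)
  if (is.null(rownames(hits)) || !all(regions %in% rownames(hits)))
    stop_("'hits' must be named/rownamed and cover every binned region")
  hits <- hits[regions, , drop = FALSE]
  N <- length(regions)
  eps <- 1 / N
  out <- list()
  for (mi in seq_len(ncol(hits))) {
    h <- hits[, mi]
    m <- sum(h)
    for (b in seq_len(bins$n_bins)) {
      in_bin <- bins$assignment == b
      k <- sum(in_bin)
      q <- sum(h[in_bin])
      p <- stats::phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
      frac_bin <- if (k > 0L) q / k else 0
      rest <- N - k
      frac_rest <- if (rest > 0L) (m - q) / rest else 0
      out[[length(out) + 1L]] <- data.frame(
        motif = colnames(hits)[mi], bin = b, n_regions = k, hit_regions = q,
        log2_enrichment = log2((frac_bin + eps) / (frac_rest + eps)),
        p = p, significant = p < p_cutoff, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
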