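#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed exactly as DESeq2 defines them:
#' for each sample, the factor is the median over reference features of
#' `count / geometric mean of that feature across samples`, where reference
#' features are those with strictly positive counts in every sample.
#'
#' @param matrix A [count_matrix()].
#' @return Named numeric vector of positive factors, one per sample.
#' @export
#' @examples
#' m <- matrix(c(10L, 20L, 40L, 80L), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, c("IMD", "D0"), c(1, 1))
#' size_factors(cm)  # ~ (0.707, 1.414)
size_factors <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  counts <- matrix$counts
  ref <- rowSums(counts > 0L) == ncol(counts)
  if (!any(ref))
    stop_("no reference features: every feature has a zero count in some sample")
  lc <- log(counts[ref, , drop = FALSE])
  lgm <- rowMeans(lc)
  sf <- apply(lc, 2L, function(x) exp(stats::median(x - lgm)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a count matrix by size factors
#'
#' Divides each sample column by its size factor, yielding the real-valued
#' normalized counts used for clustering, correlation and profiling.
#'
#' @param matrix A [count_matrix()].
#' @param factors Named positive numeric vector covering all samples;
#'   computed with [size_factors()] when omitted.
#' @return A `norm_matrix`: list with `values` (numeric matrix) and
#'   `samples` (the metadata of `matrix`).
#' @export
normalize_counts <- function(matrix, factors = size_factors(matrix)) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(names(factors))) {
    if (length(factors) != ncol(matrix$counts))
      stop_("missing size factor for some sample(s): unnamed 'factors' must ",
            "have one entry per sample")
    f <- factors
  } else {
    miss <- setdiff(colnames(matrix$counts), names(factors))
    if (length(miss)) stop_("missing size factor for sample(s): ",
                            paste(miss, collapse = ", "))
    f <- factors[colnames(matrix$counts)]
  }
  if (any(f <= 0)) stop_("size factors must be positive")
  new_norm_matrix(sweep(matrix$counts, 2L, f, "/"), matrix$samples)
}

#' Stand-in differential test between two conditions
#'
#' A documented, deliberately simple differential test used on synthetic
#' data in place of a negative-binomial GLM: the log2 fold change is the
#' pseudo-counted ratio of normalized group means,
#' `log2((mean_b + 0.5) / (mean_a + 0.5))`, and the p-value comes from a
#' Welch t-test on `log2(normalized + 1)`.  Benjamini-Hochberg adjustment
#' is applied within the comparison.  Externally computed tables (e.g.
#' DESeq2 exports) can be injected instead via [read_diff_table()].
#'
#' @param matrix A [count_matrix()].
#' @param condition_a,condition_b Condition labels; fold changes are
#'   reported as `condition_b` over `condition_a`.  Each needs at least two
#'   replicates.
#' @param factors Size factors (computed from `matrix` when omitted).
#' @return data.frame with columns `comparison` (`"a_vs_b"`),
#'   `feature_id`, `lfc`, `pvalue`, `padj`.
#' @export
differential_standin <- function(matrix, condition_a, condition_b,
                                 factors = size_factors(matrix)) {
  stopifnot(inherits(matrix, "count_matrix"))
  for (cc in c(condition_a, condition_b))
    if (sum(matrix$samples$condition == cc) < 2L)
      stop_("need >= 2 replicates of condition ", cc)
  nm <- normalize_counts(matrix, factors)
  a <- nm$values[, nm$samples$condition == condition_a, drop = FALSE]
  b <- nm$values[, nm$samples$condition == condition_b, drop = FALSE]
  lfc <- log2((rowMeans(b) + 0.5) / (rowMeans(a) + 0.5))
  la <- log2(a + 1); lb <- log2(b + 1)
  na <- ncol(a); nb <- ncol(b)
  va <- apply(la, 1L, stats::var) / na
  vb <- apply(lb, 1L, stats::var) / nb
  se2 <- va + vb
  tt <- (rowMeans(lb) - rowMeans(la)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1L) + vb^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- 1  # constant in both groups: no evidence either way
  data.frame(comparison = paste0(condition_a, "_vs_", condition_b),
             feature_id = rownames(nm$values),
             lfc = lfc, pvalue = p, padj = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH correction (with the usual monotonicity enforcement), applied
#' individually within each pairwise comparison.  Input order is preserved.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call significant features of one comparison
#'
#' Applies the significance filter used throughout: a feature is kept iff
#' `|lfc| >= lfc_min` and `padj <= padj_max` (both boundaries inclusive),
#' with direction `up` (`lfc > 0`, i.e. up in the second condition of the
#' comparison) or `down`.
#'
#' @param results data.frame from [differential_standin()] or
#'   [read_diff_table()], restricted to a single comparison.
#' @param lfc_min,padj_max Thresholds (defaults 1.5 and 0.05).
#' @return data.frame with columns `feature_id`, `lfc`, `padj`,
#'   `direction`.
#' @export
call_significant <- function(results, lfc_min = 1.5, padj_max = 0.05) {
  if (length(unique(results$comparison)) > 1L)
    stop_("'results' must contain a single comparison")
  keep <- !is.na(results$padj) &
    abs(results$lfc) >= lfc_min & results$padj <= padj_max
  out <- results[keep, c("feature_id", "lfc", "padj")]
  out$direction <- ifelse(out$lfc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Non-redundant union of significant features
#'
#' Set union of the significant feature ids over the (typically fifteen)
#' pairwise comparisons, in deterministic lexicographic order.
#'
#' @param all_comparisons Named list, one element per comparison: either a
#'   character vector of feature ids or a data.frame with a `feature_id`
#'   column (e.g. [call_significant()] output).  Names must be unique
#'   comparison labels.
#' @return Character vector of unique feature ids, sorted.
#' @export
nonredundant_union <- function(all_comparisons) {
  if (is.null(names(all_comparisons)) || anyDuplicated(names(all_comparisons)))
    stop_("comparisons must be uniquely named")
  ids <- unlist(lapply(all_comparisons, function(x)
    if (is.data.frame(x)) x$feature_id else as.character(x)), use.names = FALSE)
  sort(unique(ids), method = "radix")
}
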