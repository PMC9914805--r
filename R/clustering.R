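#' K-means archetype clustering of differential features
#'
#' Clusters the selected features of a normalized matrix into `k` archetype
#' clusters with the Hartigan-Wong K-means of [stats::kmeans()], after
#' z-scoring each feature row (mean 0, SD 1 across samples) so cluster
#' shapes are comparable across expression magnitudes.  The best of
#' `n_start` random initializations by total within-cluster sum of squares
#' is kept; results are deterministic under a fixed seed.  Rows with zero
#' variance (constant across samples) cannot be z-scored and are dropped
#' with a warning.  A run that converges with an empty cluster is simply
#' re-initialized (fresh random starts).
#'
#' @param normalized A `norm_matrix` from [normalize_counts()].
#' @param features Feature ids to cluster (e.g. a [nonredundant_union()]);
#'   default all rows.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed for the random initializations.
#' @param n_start Number of random starts (default 25).
#' @param collapse_replicates If `TRUE`, cluster per-condition replicate
#'   means instead of per-sample columns.
#' @return Object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector, labels `1..k`), `k`, `centers` (k x columns),
#'   `inertia` (total within-cluster SS), `dropped` (ids of constant rows)
#'   and `algorithm`.
#' @export
kmeans_features <- function(normalized, features = NULL, k = 6L, seed = NULL,
                            n_start = 25L, collapse_replicates = FALSE) {
  stopifnot(inherits(normalized, "norm_matrix"))
  x <- normalized$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(x))
    if (length(miss)) stop_("features absent from matrix: ",
                            paste(utils::head(miss, 3L), collapse = ", "))
    x <- x[features, , drop = FALSE]
  }
  if (collapse_replicates) x <- condition_means(x, normalized$samples)
  rsd <- apply(x, 1L, stats::sd)
  dropped <- rownames(x)[rsd == 0]
  if (length(dropped)) {
    warning(length(dropped), " constant feature(s) dropped before z-scoring",
            call. = FALSE)
    x <- x[rsd > 0, , drop = FALSE]
  }
  if (nrow(x) < k) stop_("k = ", k, " exceeds the ", nrow(x),
                         " clusterable features")
  z <- t(scale(t(x)))  # row z-scores
  if (!is.null(seed)) set.seed(seed)
  fit <- NULL
  for (attempt in 1:20) {
    fit <- tryCatch(
      stats::kmeans(z, centers = k, nstart = n_start, iter.max = 100L,
                    algorithm = "Hartigan-Wong"),
      error = function(e) {
        if (grepl("empty cluster", conditionMessage(e))) NULL else stop(e)
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop_("k-means failed to converge without empty clusters")
  structure(
    list(cluster = stats::setNames(as.integer(fit$cluster), rownames(z)),
         k = as.integer(k),
         centers = fit$centers,
         inertia = fit$tot.withinss,
         dropped = dropped,
         algorithm = "Hartigan-Wong"),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d features in k = %d clusters (%s), inertia %.1f\n",
              length(x$cluster), x$k, x$algorithm, x$inertia))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Per-cluster mean z-score profile by condition
#'
#' For each cluster and condition, the mean over member features and
#' replicates of the row-z-scored normalized values: the archetype shape a
#' cluster heatmap displays.
#'
#' @param assignment A `cluster_assignment` from [kmeans_features()].
#' @param normalized The `norm_matrix` the assignment was computed from.
#' @return k x conditions numeric matrix.
#' @export
cluster_condition_profile <- function(assignment, normalized) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(normalized, "norm_matrix"))
  ids <- names(assignment$cluster)
  miss <- setdiff(ids, rownames(normalized$values))
  if (length(miss)) stop_("assignment features absent from matrix")
  z <- t(scale(t(normalized$values[ids, , drop = FALSE])))
  zc <- condition_means(z, normalized$samples)
  out <- t(vapply(seq_len(assignment$k), function(cl) {
    colMeans(zc[assignment$cluster == cl, , drop = FALSE])
  }, numeric(ncol(zc))))
  rownames(out) <- paste0("C", seq_len(assignment$k))
  out
}
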