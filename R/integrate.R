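#' Match peaks to genes by nearest promoter
#'
#' Builds the peak-to-gene map from annotation records: each peak is
#' assigned the gene with the nearest TSS (the `nearest_gene` of
#' [annotate_peaks()], which breaks exact-distance ties by
#' lexicographically smaller gene id).  Peaks with no gene (off-annotation
#' chromosomes) are excluded and counted.
#'
#' @param records data.frame from [annotate_peaks()].
#' @return Object of class `peak_gene_map`: list with `peaks` (data.frame
#'   `peak_id`, `gene_id`, `tss_distance`), `genes` (named list gene ->
#'   peak ids) and `n_unmapped`.
#' @export
match_peaks_to_genes <- function(records) {
  keep <- !is.na(records$nearest_gene)
  pk <- data.frame(peak_id = records$peak_id[keep],
                   gene_id = records$nearest_gene[keep],
                   tss_distance = records$tss_distance[keep],
                   stringsAsFactors = FALSE)
  structure(list(peaks = pk,
                 genes = split(pk$peak_id, pk$gene_id),
                 n_unmapped = sum(!keep)),
            class = "peak_gene_map")
}

#' @export
print.peak_gene_map <- function(x, ...) {
  cat(sprintf("peak_gene_map: %d peaks -> %d genes (%d unmapped)\n",
              nrow(x$peaks), length(x$genes), x$n_unmapped))
  invisible(x)
}

#' Gene-level accessibility matrix
#'
#' Collapses a normalized ATAC peak matrix to gene level: for each gene
#' and sample, the arithmetic mean of the normalized counts of the peaks
#' mapped to that gene.  Genes with no mapped peak are absent from the
#' output.
#'
#' @param normalized `norm_matrix` of normalized ATAC peak counts.
#' @param map A [match_peaks_to_genes()] result.
#' @return `norm_matrix` with genes as rows.
#' @export
gene_level_atac <- function(normalized, map) {
  stopifnot(inherits(normalized, "norm_matrix"),
            inherits(map, "peak_gene_map"))
  pk <- map$peaks[map$peaks$peak_id %in% rownames(normalized$values), ]
  if (!nrow(pk)) stop_("no mapped peaks present in the matrix")
  v <- normalized$values[pk$peak_id, , drop = FALSE]
  sums <- rowsum(v, group = pk$gene_id)
  nper <- as.vector(table(pk$gene_id)[rownames(sums)])
  new_norm_matrix(sums / nper, normalized$samples)
}

#' Global expression-accessibility correlation
#'
#' Pearson correlation over all (gene, condition) pairs between normalized
#' expression and gene-level promoter accessibility.  Because the RNA and
#' ATAC designs have unequal replicate counts (3 vs 2), samples are paired
#' at condition level using per-condition replicate means.  Values are
#' `log2(x + 1)` transformed by default, the standard scale for pooled
#' correlation of count data spanning orders of magnitude; set
#' `log2 = FALSE` for the raw normalized scale.
#'
#' @param rna `norm_matrix` of normalized expression.
#' @param atac `norm_matrix` from [gene_level_atac()].
#' @param log2 Transform both sides with `log2(x + 1)` first (default).
#' @return Pearson r (numeric scalar).
#' @export
global_correlation <- function(rna, atac, log2 = TRUE) {
  m <- paired_condition_matrices(rna, atac, log2)
  if (length(m$x) < 2L) stop_("fewer than 2 paired values")
  stats::cor(as.vector(m$x), as.vector(m$y))
}

paired_condition_matrices <- function(rna, atac, log2) {
  stopifnot(inherits(rna, "norm_matrix"), inherits(atac, "norm_matrix"))
  genes <- intersect(rownames(rna$values), rownames(atac$values))
  if (!length(genes)) stop_("no shared genes")
  x <- condition_means(rna$values[genes, , drop = FALSE], rna$samples)
  y <- condition_means(atac$values[genes, , drop = FALSE], atac$samples)
  conds <- intersect(colnames(x), colnames(y))
  x <- x[, conds, drop = FALSE]
  y <- y[, conds, drop = FALSE]
  if (log2) { x <- log2(x + 1); y <- log2(y + 1) }
  list(x = x, y = y, genes = genes, conditions = conds)
}

#' Per-gene correlation with category labels
#'
#' Pearson correlation per gene, across condition-mean pairs, between
#' expression and gene-level accessibility, binned into five categories by
#' configurable thresholds: `strong` for `|r| >= strong`, `moderate` for
#' `moderate <= |r| < strong`, else `none`.  Genes with a zero-variance
#' vector on either side have undefined r and are categorized `none`.
#'
#' @inheritParams global_correlation
#' @param strong,moderate Absolute-r thresholds (defaults 0.9 and 0.5).
#' @return data.frame with `gene_id`, `r`, `category` (factor:
#'   `strong_positive`, `moderate_positive`, `none`, `moderate_negative`,
#'   `strong_negative`).
#' @export
per_gene_correlation_categories <- function(rna, atac, strong = 0.9,
                                            moderate = 0.5, log2 = TRUE) {
  m <- paired_condition_matrices(rna, atac, log2)
  if (ncol(m$x) < 3L) stop_("need at least 3 shared conditions")
  r <- vapply(seq_along(m$genes), function(i) {
    xi <- m$x[i, ]; yi <- m$y[i, ]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) return(NA_real_)
    stats::cor(xi, yi)
  }, numeric(1L))
  lvl <- c("strong_positive", "moderate_positive", "none",
           "moderate_negative", "strong_negative")
  category <- rep("none", length(r))
  category[!is.na(r) & r >= strong] <- "strong_positive"
  category[!is.na(r) & r >= moderate & r < strong] <- "moderate_positive"
  category[!is.na(r) & r <= -strong] <- "strong_negative"
  category[!is.na(r) & r <= -moderate & r > -strong] <- "moderate_negative"
  data.frame(gene_id = m$genes, r = r,
             category = factor(category, levels = lvl),
             stringsAsFactors = FALSE)
}

#' Cluster co-membership cross-table
#'
#' Counts genes by joint (RNA cluster, ATAC cluster) membership.  A gene's
#' ATAC cluster is the cluster of its mapped peak; for genes with several
#' mapped peaks the nearest peak (smallest `|tss_distance|`, ties by peak
#' id) decides by default, or the majority cluster with
#' `multi_peak = "majority"`.  When `map` is `NULL` the two label vectors
#' are matched directly by name (or position).
#'
#' @param rna_clusters Named vector, gene -> cluster label `1..k` (e.g.
#'   the `cluster` element of [kmeans_features()]).
#' @param atac_clusters Named vector, peak (or gene, when `map` is `NULL`)
#'   -> cluster label.
#' @param map Optional [match_peaks_to_genes()] result linking peaks to
#'   genes.
#' @param multi_peak `"nearest"` (default) or `"majority"`.
#' @return Object of class `cross_table`: integer matrix, rows
#'   `C1..Ck` (RNA clusters), columns `CA..CF...` (ATAC clusters), with
#'   attribute `n_total`.
#' @export
cross_table <- function(rna_clusters, atac_clusters, map = NULL,
                        multi_peak = c("nearest", "majority")) {
  multi_peak <- match.arg(multi_peak)
  if (!is.null(map)) {
    stopifnot(inherits(map, "peak_gene_map"))
    pk <- map$peaks[map$peaks$peak_id %in% names(atac_clusters), ]
    pk$cluster <- atac_clusters[pk$peak_id]
    gene_atac <- vapply(split(pk, pk$gene_id), function(d) {
      if (multi_peak == "nearest") {
        d <- d[order(abs(d$tss_distance), d$peak_id), ]
        d$cluster[1L]
      } else {
        tt <- sort(table(d$cluster), decreasing = TRUE)
        as.integer(names(tt)[1L])
      }
    }, numeric(1L))
  } else {
    gene_atac <- atac_clusters
  }
  if (!is.null(names(rna_clusters)) && !is.null(names(gene_atac))) {
    genes <- intersect(names(rna_clusters), names(gene_atac))
    if (!length(genes)) stop_("label vectors share no ids")
    r <- rna_clusters[genes]; a <- gene_atac[genes]
  } else {
    if (length(rna_clusters) != length(gene_atac))
      stop_("unnamed label vectors must have equal length")
    r <- rna_clusters; a <- gene_atac
  }
  kr <- max(r); ka <- max(a)
  tab <- table(factor(r, levels = seq_len(kr)), factor(a, levels = seq_len(ka)))
  out <- matrix(as.integer(tab), kr, ka,
                dimnames = list(paste0("C", seq_len(kr)),
                                paste0("C", LETTERS[seq_len(ka)])))
  class(out) <- c("cross_table", class(out))
  attr(out, "n_total") <- sum(out)
  out
}

#' @export
print.cross_table <- function(x, ...) {
  cat(sprintf("cross_table of %d genes (RNA clusters x ATAC clusters)\n",
              attr(x, "n_total")))
  print(unclass(x)[, ])
  invisible(x)
}

#' Chi-squared test of cluster-set independence
#'
#' Pearson chi-squared on a [cross_table()], df = (k-1)(k-1), no
#' continuity correction.
#'
#' @param table A `cross_table` (or plain count matrix).
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
chi_squared_independence <- function(table) {
  m <- unclass(table)
  attr(m, "n_total") <- NULL
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected)
}

#' Fixed-margin permutation test of cluster association
#'
#' The permutation analysis applied to the cluster cross-table: keeping
#' cluster sizes fixed, one label vector is uniformly permuted `n_perm`
#' times (distributionally identical to permuting both, since only the
#' relative alignment matters) and a cross-table is tallied each time.
#' Per cell, `empirical_p` is the fraction of permutations whose count is
#' greater than or equal to the observed count, and a cell is *associated*
#' when `empirical_p < alpha` (the "fewer than 5 percent of permuted
#' counts" rule).  No multiple-testing correction across cells is applied.
#' Under this single-vector permutation null each cell count is
#' hypergeometric, which serves as the analytic cross-check in the tests.
#'
#' @param rna_labels,atac_labels Cluster label vectors (`1..k`) over the
#'   same gene universe; matched by names when both are named.
#' @param n_perm Number of permutations (default 100000).
#' @param alpha Per-cell association threshold (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `association_result`: list with `observed`,
#'   `expected` (margin product / N), `empirical_p`, `associated`
#'   (all k x k matrices), `n_perm`, `alpha`, `seed`, `n_total`.
#' @export
permutation_association <- function(rna_labels, atac_labels, n_perm = 100000L,
                                    alpha = 0.05, seed = NULL) {
  if (n_perm < 1L) stop_("n_perm must be >= 1")
  if (!is.null(names(rna_labels)) && !is.null(names(atac_labels))) {
    genes <- intersect(names(rna_labels), names(atac_labels))
    if (!length(genes)) stop_("label vectors share no ids")
    r <- as.integer(rna_labels[genes]); a <- as.integer(atac_labels[genes])
  } else {
    if (length(rna_labels) != length(atac_labels))
      stop_("unnamed label vectors must have equal length")
    r <- as.integer(rna_labels); a <- as.integer(atac_labels)
  }
  n <- length(r)
  kr <- max(r); ka <- max(a)
  ncell <- kr * ka
  code <- (r - 1L) * ka
  obs <- tabulate(code + a, nbins = ncell)
  if (!is.null(seed)) set.seed(seed)
  hits <- integer(ncell)
  for (i in seq_len(n_perm)) {
    perm <- a[sample.int(n)]
    hits <- hits + (tabulate(code + perm, nbins = ncell) >= obs)
  }
  dn <- list(paste0("C", seq_len(kr)), paste0("C", LETTERS[seq_len(ka)]))
  shape <- function(v) matrix(v, kr, ka, byrow = TRUE, dimnames = dn)
  expected <- outer(tabulate(r, kr), tabulate(a, ka)) / n
  dimnames(expected) <- dn
  emp <- shape(hits / n_perm)
  structure(list(observed = shape(obs), expected = expected,
                 empirical_p = emp, associated = emp < alpha,
                 n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
                 n_total = n),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: %d genes, %d permutations, alpha %.3g\n",
              x$n_total, x$n_perm, x$alpha))
  cat("associated cells (empirical p <", x$alpha, "):\n")
  print(which(x$associated, arr.ind = TRUE))
  invisible(x)
}

#' Direction-concordance table between modalities
#'
#' For one culture-medium-vs-differentiation-medium comparison (at a given
#' day), tallies genes into a 3 x 3 table by their RNA direction (up in
#' the first condition / no difference / up in the second) against the
#' ATAC direction of their promoter peak.  Directions come from
#' [call_significant()] thresholds applied to each modality's differential
#' results; the ATAC direction of a gene is that of its nearest mapped
#' peak among peaks in the ATAC test universe.  Genes absent from either
#' modality's universe are excluded and counted.
#'
#' @param rna_results,atac_results Differential tables (single comparison
#'   each), as from [differential_standin()]; `lfc > 0` means up in the
#'   second condition of the comparison.
#' @param map A [match_peaks_to_genes()] result.
#' @param lfc_min,padj_max Significance thresholds.
#' @return 3 x 3 integer matrix; rows are RNA status, columns ATAC status,
#'   labels `up_<a>`, `no_difference`, `up_<b>` from the comparison
#'   conditions; attribute `n_excluded`.
#' @export
direction_concordance <- function(rna_results, atac_results, map,
                                  lfc_min = 1.5, padj_max = 0.05) {
  stopifnot(inherits(map, "peak_gene_map"))
  comp <- unique(rna_results$comparison)
  if (length(comp) != 1L) stop_("'rna_results' must hold a single comparison")
  ab <- strsplit(comp, "_vs_", fixed = TRUE)[[1L]]
  status <- function(res) {
    sig <- call_significant(res, lfc_min, padj_max)
    s <- stats::setNames(rep("no_difference", nrow(res)), res$feature_id)
    s[sig$feature_id[sig$direction == "down"]] <- "up_a"
    s[sig$feature_id[sig$direction == "up"]] <- "up_b"
    s
  }
  rna_s <- status(rna_results)
  atac_s <- status(atac_results)
  pk <- map$peaks[map$peaks$peak_id %in% names(atac_s), ]
  pk <- pk[order(pk$gene_id, abs(pk$tss_distance), pk$peak_id), ]
  pk <- pk[!duplicated(pk$gene_id), ]  # nearest in-universe peak per gene
  gene_atac <- stats::setNames(atac_s[pk$peak_id], pk$gene_id)
  genes <- intersect(names(rna_s), names(gene_atac))
  lv <- c("up_a", "no_difference", "up_b")
  lab <- c(paste0("up_", ab[1L]), "no_difference", paste0("up_", ab[2L]))
  tab <- table(factor(rna_s[genes], levels = lv),
               factor(gene_atac[genes], levels = lv))
  out <- matrix(as.integer(tab), 3L, 3L, dimnames = list(RNA = lab, ATAC = lab))
  attr(out, "n_excluded") <- length(rna_s) - length(genes)
  out
}

#' Fisher exact test of direction-set association
#'
#' Two-sided Fisher exact test on the 2 x 2 table of down/up-regulated
#' counts in two gene sets (exact p by summing hypergeometric
#' probabilities no larger than the observed table's).
#'
#' @param set_a_down,set_a_up,set_b_down,set_b_up Nonnegative integer
#'   cell counts (rows: gene sets; columns: down/up).
#' @return List with `p.value` and `table`.
#' @export
#' @examples
#' fisher_direction_test(20, 2, 0, 5)$p.value  # ~ 0.0003
fisher_direction_test <- function(set_a_down, set_a_up, set_b_down, set_b_up) {
  tab <- matrix(c(set_a_down, set_a_up, set_b_down, set_b_up), 2L, 2L,
                byrow = TRUE,
                dimnames = list(set = c("a", "b"), c("down", "up")))
  if (any(tab < 0) || any(tab != round(tab))) stop_("counts must be nonnegative integers")
  if (sum(tab) == 0L) stop_("all-zero table")
  list(p.value = stats::fisher.test(tab)$p.value, table = tab)
}

#' TSS metaprofiles by expression quintile
#'
#' For each condition, ranks genes by mean normalized expression
#' (replicates collapsed by mean), splits them into five equal-size
#' quintiles (any remainder goes to the lowest-expression quintiles; ties
#' broken by a stable sort on feature id) and averages the TSS-centred
#' accessibility signal per position bin within each quintile.
#'
#' @param coverage A `tss_coverage` object (see [simulate_tss_coverage()]):
#'   per-sample gene x bin signal matrices, already oriented so upstream
#'   is left.
#' @param rna `norm_matrix` of normalized expression sharing gene ids with
#'   `coverage`.
#' @param n_quantiles Number of expression bins (default 5).
#' @return Named list, one `n_quantiles` x bins matrix per condition; rows
#'   `Q1` (highest expression) to `Q5`; attribute `positions` gives bin
#'   centre offsets from the TSS.
#' @export
tss_quintile_profiles <- function(coverage, rna, n_quantiles = 5L) {
  stopifnot(inherits(coverage, "tss_coverage"), inherits(rna, "norm_matrix"))
  genes <- intersect(coverage$gene_ids, rownames(rna$values))
  if (length(genes) < n_quantiles)
    stop_("need at least ", n_quantiles, " shared genes")
  expr <- condition_means(rna$values[genes, , drop = FALSE], rna$samples)
  # collapse coverage replicates by condition mean
  conds <- intersect(colnames(expr),
                     unique(coverage$samples$condition))
  out <- list()
  for (cc in conds) {
    sids <- coverage$samples$sample_id[coverage$samples$condition == cc]
    sig <- Reduce(`+`, lapply(sids, function(s)
      coverage$signal[[s]][genes, , drop = FALSE])) / length(sids)
    ord <- order(-expr[, cc], genes, method = "radix")
    base <- length(genes) %/% n_quantiles
    extra <- length(genes) %% n_quantiles
    # remainder goes to the lowest-expression quantiles
    sizes <- base + c(rep(0L, n_quantiles - extra), rep(1L, extra))
    grp <- rep(seq_len(n_quantiles), sizes)
    prof <- rowsum(sig[ord, , drop = FALSE], group = grp) /
      as.vector(table(grp))
    rownames(prof) <- paste0("Q", seq_len(n_quantiles))
    out[[cc]] <- prof
  }
  attr(out, "positions") <- coverage$positions
  out
}
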