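test_that("peak-to-gene matching follows nearest promoter with tie-break", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      strand = c("+", "+"),
                      start = c(10000L, 30000L), end = c(12000L, 32000L))
  exons <- data.frame(gene_id = c("gB", "gA"),
                      start = c(10000L, 30000L), end = c(12000L, 32000L),
                      rank = c(1L, 1L))
  ann <- gene_annotation(genes, exons)
  pk <- rbind(peak_at(10000, "at_tss"), peak_at(20000, "equidistant"))
  rec <- annotate_peaks(pk, ann)
  map <- match_peaks_to_genes(rec)
  expect_equal(map$peaks$gene_id[map$peaks$peak_id == "at_tss"], "gB")
  expect_equal(map$peaks$tss_distance[map$peaks$peak_id == "at_tss"], 0L)
  # exactly between both TSSs: lexicographically smaller gene id wins
  expect_equal(map$peaks$gene_id[map$peaks$peak_id == "equidistant"], "gA")
})

test_that("peak-to-gene map equals brute-force nearest-TSS search", {
  x <- tiny_sim()
  rec <- annotate_peaks(x$sim$peaks, x$ann)
  map <- match_peaks_to_genes(rec)
  tss <- x$ann$genes$tss
  gid <- x$ann$genes$gene_id
  anchor <- x$sim$peaks$summit
  for (i in seq_len(nrow(x$sim$peaks))) {
    d <- abs(anchor[i] - tss)
    want <- sort(gid[d == min(d)])[1]
    expect_equal(map$peaks$gene_id[map$peaks$peak_id ==
                                     x$sim$peaks$peak_id[i]], want)
  }
})

test_that("gene-level accessibility is the mean over mapped peaks", {
  vals <- matrix(c(2, 4, 6, 10, 1, 1), 3, 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  nm <- crosspeak:::new_norm_matrix(
    vals, data.frame(sample_id = c("s1", "s2"),
                     condition = c("IMD", "IMD"), replicate = 1:2))
  map <- structure(list(
    peaks = data.frame(peak_id = c("p1", "p2", "p3"),
                       gene_id = c("g1", "g1", "g2"),
                       tss_distance = c(10L, -20L, 0L)),
    genes = list(g1 = c("p1", "p2"), g2 = "p3"), n_unmapped = 0L),
    class = "peak_gene_map")
  gl <- gene_level_atac(nm, map)
  expect_equal(gl$values["g1", ], c(s1 = 4, s2 = 7))   # mean of (2,6) and (4,10)
  expect_equal(gl$values["g2", ], c(s1 = 1, s2 = 1))   # single peak passthrough

  # oracle: group means on the synthetic map
  x <- tiny_sim()
  nma <- normalize_counts(x$sim$atac)
  rec <- annotate_peaks(x$sim$peaks, x$ann)
  m2 <- match_peaks_to_genes(rec)
  gl2 <- gene_level_atac(nma, m2)
  g <- sample(rownames(gl2$values), 5)
  for (gg in g) {
    pks <- m2$genes[[gg]]
    expect_equal(gl2$values[gg, ],
                 colMeans(nma$values[pks, , drop = FALSE]))
  }
})

test_that("global correlation hits the exact limits", {
  x <- tiny_sim()
  nm <- normalize_counts(x$sim$rna)
  same <- nm
  expect_equal(global_correlation(nm, same), 1.0)
  neg <- nm
  neg$values <- -nm$values + max(nm$values)
  expect_equal(global_correlation(nm, neg, log2 = FALSE), -1.0)
})

test_that("per-gene correlation categories handle exact and degenerate cases", {
  conds <- explant_conditions()
  vals <- rbind(gUp = c(1, 2, 3, 4, 5, 6),
                gFlat = rep(4, 6),
                gDown = c(6, 5, 4, 3, 2, 1))
  colnames(vals) <- paste0(conds, "_1")
  smp <- data.frame(sample_id = colnames(vals), condition = conds,
                    replicate = 1L)
  rna <- crosspeak:::new_norm_matrix(vals, smp)
  atac <- crosspeak:::new_norm_matrix(
    rbind(gUp = c(1, 2, 3, 4, 5, 6), gFlat = rep(2, 6),
          gDown = c(1, 2, 3, 4, 5, 6)), smp)
  rownames(atac$values) <- c("gUp", "gFlat", "gDown")
  colnames(atac$values) <- colnames(vals)
  pc <- per_gene_correlation_categories(rna, atac, log2 = FALSE)
  expect_equal(as.character(pc$category[pc$gene_id == "gUp"]), "strong_positive")
  expect_equal(as.character(pc$category[pc$gene_id == "gFlat"]), "none")
  expect_true(is.na(pc$r[pc$gene_id == "gFlat"]))
  expect_equal(as.character(pc$category[pc$gene_id == "gDown"]), "strong_negative")
})

test_that("per-gene correlation survives per-gene rescaling, global does not", {
  # rescaling a gene's values (in either or both modalities) rescales both
  # vectors wholesale, so its per-gene Pearson r is untouched; the pooled
  # global r mixes genes and is not invariant
  x <- tiny_sim()
  nm <- normalize_counts(x$sim$rna)
  rec <- annotate_peaks(x$sim$peaks, x$ann)
  gl <- gene_level_atac(normalize_counts(x$sim$atac), match_peaks_to_genes(rec))
  pc1 <- per_gene_correlation_categories(nm, gl, log2 = FALSE)
  g1 <- global_correlation(nm, gl, log2 = FALSE)
  scale_genes <- function(m, genes, c) {
    i <- rownames(m$values) %in% genes
    m$values[i, ] <- m$values[i, ] * c
    m
  }
  some <- rownames(gl$values)[1:20]
  nm2 <- scale_genes(nm, some, 25)
  gl2 <- scale_genes(gl, some, 0.04)
  pc2 <- per_gene_correlation_categories(nm2, gl2, log2 = FALSE)
  g2 <- global_correlation(nm2, gl2, log2 = FALSE)
  expect_false(isTRUE(all.equal(g1, g2)))
  expect_equal(pc2$r, pc1$r, tolerance = 1e-12)
})

test_that("cross-tables tally joint membership and reproduce printed margins", {
  r <- setNames(c(1, 1, 2, 2), paste0("g", 1:4))
  a <- setNames(c(1, 1, 2, 2), paste0("g", 1:4))
  ct <- cross_table(r, a)
  expect_equal(unclass(ct)[, ], matrix(c(2L, 0L, 0L, 2L), 2,
                                       dimnames = list(c("C1", "C2"),
                                                       c("CA", "CB"))))
  tab <- table1_counts()
  lab <- labels_from_table(tab)
  ct2 <- cross_table(lab$rna, lab$atac)
  expect_equal(sum(ct2["C1", ]), 908)   # printed row C1 re-summed
  expect_equal(attr(ct2, "n_total"), 7193)
  expect_equal(unclass(ct2)[, ], tab, ignore_attr = TRUE)
})

test_that("cross_table resolves multi-peak genes by the nearest peak", {
  map <- structure(list(
    peaks = data.frame(peak_id = c("pNear", "pFar"),
                       gene_id = c("g1", "g1"),
                       tss_distance = c(100L, -5000L)),
    genes = list(g1 = c("pNear", "pFar")), n_unmapped = 0L),
    class = "peak_gene_map")
  ct <- cross_table(setNames(1L, "g1"),
                    c(pNear = 2L, pFar = 1L), map = map)
  expect_equal(unclass(ct)["C1", "CB"], 1L)
  expect_equal(sum(ct), 1L)
})

test_that("chi-squared independence matches the hand computation", {
  prop <- matrix(c(10, 20, 30, 60), 2)  # perfectly proportional
  out <- chi_squared_independence(prop)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p.value, 1)

  diag2 <- chi_squared_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$statistic, 20)
  expect_equal(diag2$df, 1)

  tab <- table1_counts()
  out2 <- chi_squared_independence(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out2$statistic, sum((tab - e)^2 / e))
  expect_equal(out2$df, 25)
  expect_error(chi_squared_independence(matrix(c(1, 1, 0, 0), 2)), "margin")
})

test_that("permutation p-values match the hypergeometric tail", {
  set.seed(19)
  n <- 400
  r <- sample(1:3, n, replace = TRUE)
  a <- sample(1:3, n, replace = TRUE)
  ar <- permutation_association(r, a, n_perm = 4000, seed = 7)
  for (i in 1:3) for (j in 1:3) {
    m <- sum(r == i); k <- sum(a == j)
    ph <- phyper(ar$observed[i, j] - 1, k, n - k, m, lower.tail = FALSE)
    tol <- 3 * sqrt(ph * (1 - ph) / 4000) + 1 / 4000
    expect_lt(abs(ar$empirical_p[i, j] - ph), tol)
  }
  expect_equal(ar$expected,
               outer(tabulate(r, 3), tabulate(a, 3)) / n, ignore_attr = TRUE)
})

test_that("a saturated cell is always flagged associated", {
  # cluster 1 of RNA(5 genes) all sit in ATAC cluster 1 (margin also 5)
  r <- c(rep(1, 5), rep(2, 45))
  a <- c(rep(1, 5), rep(2, 45))
  ar <- permutation_association(r, a, n_perm = 2000, seed = 1)
  expect_true(ar$associated[1, 1])
  expect_identical(max(ar$observed[1, 1]), 5L)
})

test_that("Fisher direction test matches enumeration and exact limits", {
  expect_equal(fisher_direction_test(5, 5, 5, 5)$p.value, 1.0)
  set.seed(8)
  for (i in 1:12) {
    cells <- as.vector(rmultinom(1, sample(8:40, 1), prob = rep(1 / 4, 4)))
    got <- fisher_direction_test(cells[1], cells[2], cells[3], cells[4])$p.value
    expect_equal(got, oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_direction_test(0, 0, 0, 0), "all-zero")
})

test_that("direction concordance tallies genes by modality status", {
  rna <- data.frame(comparison = "D5_CM_vs_D5_DM",
                    feature_id = paste0("g", 1:4),
                    lfc = c(3, -3, 0.1, 3), pvalue = 0.001,
                    padj = c(0.01, 0.01, 0.9, 0.01))
  atac <- data.frame(comparison = "D5_CM_vs_D5_DM",
                     feature_id = paste0("p", 1:4),
                     lfc = c(3, -3, 0.1, 3), pvalue = 0.001,
                     padj = c(0.01, 0.01, 0.9, 0.01))
  map <- structure(list(
    peaks = data.frame(peak_id = paste0("p", 1:4),
                       gene_id = paste0("g", 1:4),
                       tss_distance = rep(0L, 4)),
    genes = as.list(setNames(paste0("p", 1:4), paste0("g", 1:4))),
    n_unmapped = 0L), class = "peak_gene_map")
  tab <- direction_concordance(rna, atac, map)
  expect_equal(dimnames(tab)$RNA,
               c("up_D5_CM", "no_difference", "up_D5_DM"))
  expect_equal(tab["up_D5_DM", "up_D5_DM"], 2L)  # g1 and g4 concordant up
  expect_equal(tab["up_D5_CM", "up_D5_CM"], 1L)
  expect_equal(tab["no_difference", "no_difference"], 1L)
  expect_equal(sum(tab), 4L)
})

test_that("quintile profiles are rank-invariant and collapse ties sensibly", {
  x <- tiny_sim()
  cfg <- x$cfg
  cov <- simulate_tss_coverage(cfg, x$ann, x$sim$rna)
  nm <- normalize_counts(x$sim$rna)
  qp <- tss_quintile_profiles(cov, nm)
  expect_equal(rownames(qp$IMD), paste0("Q", 1:5))

  # permuting gene order in the expression matrix changes nothing
  perm <- sample(nrow(nm$values))
  nm2 <- nm; nm2$values <- nm$values[perm, , drop = FALSE]
  qp2 <- tss_quintile_profiles(cov, nm2)
  expect_equal(qp2, qp)

  # identical coverage for all genes -> five identical profiles
  cov3 <- cov
  for (s in names(cov3$signal)) {
    m <- cov3$signal[[s]]
    cov3$signal[[s]] <- matrix(rep(m[1, ], each = nrow(m)), nrow(m),
                               dimnames = dimnames(m))
  }
  qp3 <- tss_quintile_profiles(cov3, nm)
  for (q in 2:5) expect_equal(qp3$IMD[q, ], qp3$IMD[1, ])

  few <- nm; few$values <- nm$values[1:3, , drop = FALSE]
  expect_error(tss_quintile_profiles(cov, few), "at least 5")
})

test_that("quintile profiles order with expression-proportional amplitude", {
  cfg <- sim_config(seed = 13, n_genes = 100, n_peaks = 100,
                    chrom_sizes = c(chr1 = 2.2e6), coverage_noise = 0)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  cov <- simulate_tss_coverage(cfg, ann, sim$rna)
  qp <- tss_quintile_profiles(cov, normalize_counts(sim$rna))
  centre <- which(cov$positions == 0)
  for (cc in names(qp)) {
    v <- qp[[cc]][, centre]
    expect_true(all(diff(v) < 0))  # strictly ordered Q1 > ... > Q5
  }
})
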