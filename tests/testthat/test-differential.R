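make_cm <- function(counts, conds, reps = NULL) {
  if (is.null(reps)) reps <- stats::ave(seq_along(conds), conds, FUN = seq_along)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  colnames(counts) <- paste0(conds, "_", reps)
  count_matrix(counts, conds, reps)
}

test_that("size factors follow the median-of-ratios definition", {
  # every feature (x, 2x): geometric-mean reference sqrt(2) x
  m <- matrix(c(10L, 20L, 50L, 100L, 7L, 14L), 3, 2, byrow = TRUE)
  cm <- make_cm(m, c("IMD", "D0"))
  expect_equal(unname(size_factors(cm)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  ident <- make_cm(matrix(rep(5:9, 3), 5, 3), c("IMD", "IMD", "D0"))
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  expect_error(size_factors(make_cm(matrix(c(0L, 1L, 2L, 0L), 2), c("IMD", "D0"))),
               "no reference features")
})

test_that("size factors normalize ratio medians to one and scale equivariantly", {
  set.seed(21)
  m <- matrix(rnbinom(500 * 6, mu = 200, size = 10) + 1L, 500, 6)
  cm <- make_cm(m, rep(c("IMD", "D0", "D5_CM"), each = 2))
  sf <- size_factors(cm)
  lgm <- rowMeans(log(m))
  norm <- sweep(m, 2, sf, "/")
  med <- apply(log(norm) - lgm, 2, median)
  # definitional property: per-sample median log ratio to reference ~ common shift
  expect_true(all(abs(med - mean(med)) < 1e-9))

  # scaling one sample by c scales its factor by c, up to the global
  # geometric-mean renormalization c^(1/n) shared by all samples
  m2 <- m; m2[, 3] <- m2[, 3] * 5L
  sf2 <- size_factors(make_cm(m2, rep(c("IMD", "D0", "D5_CM"), each = 2)))
  shift <- 5^(1 / 6)
  expect_equal(unname(sf2[3] / sf[3]), 5 / shift, tolerance = 1e-12)
  expect_equal(unname(sf2[-3]), unname(sf[-3]) / shift, tolerance = 1e-12)
  # so normalized ratios between samples are exactly scale-equivariant
  expect_equal(unname(sf2[3] / sf2[1]), unname(5 * sf[3] / sf[1]),
               tolerance = 1e-12)
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  m <- matrix(rnbinom(300 * 6, mu = 150, size = 5) + 1L, 300, 6)
  cm <- make_cm(m, rep(c("IMD", "D1_CM", "D1_DM"), each = 2))
  expect_equal(unname(size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(cm$counts)),
               tolerance = 1e-10)
})

test_that("normalization divides columns and is invariant to matched scaling", {
  m <- matrix(c(4L, 8L, 6L, 12L), 2, 2)
  cm <- make_cm(m, c("IMD", "D0"))
  nm1 <- normalize_counts(cm, c(1, 1))
  expect_equal(nm1$values, cm$counts + 0, ignore_attr = TRUE)
  expect_equal(normalize_counts(cm, setNames(c(2, 3), colnames(cm$counts)))$
                 values[1, 2], 6 / 3)
  # doubling a column and its factor leaves the normalized column unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  cm2 <- make_cm(m2, c("IMD", "D0"))
  expect_equal(normalize_counts(cm2, c(1, 2))$values,
               normalize_counts(cm, c(1, 1))$values, ignore_attr = TRUE)
  expect_error(normalize_counts(cm, c(a = 1)), "missing size factor")
})

test_that("stand-in differential test recovers planted fold changes", {
  # vanishing dispersion: counts are exactly the planted means
  n <- 50
  counts <- cbind(matrix(100L, n, 3), matrix(800L, n, 3))
  cm <- make_cm(counts, rep(c("D0", "D1_DM"), each = 3))
  res <- differential_standin(cm, "D0", "D1_DM", factors = rep(1, 6))
  expect_true(all(abs(res$lfc - 3) < 0.2))  # log2(800.5/100.5) = 2.994

  set.seed(2)
  noisy <- cbind(matrix(rpois(n * 3, 100), n), matrix(rpois(n * 3, 800), n))
  resn <- differential_standin(make_cm(noisy, rep(c("D0", "D1_DM"), each = 3)),
                               "D0", "D1_DM", factors = rep(1, 6))
  expect_lt(abs(mean(resn$lfc) - 3), 0.1)

  same <- make_cm(cbind(noisy[, 1:3], noisy[, 1:3]),
                  rep(c("D0", "D1_DM"), each = 3))
  res0 <- differential_standin(same, "D0", "D1_DM", factors = rep(1, 6))
  expect_true(all(res0$lfc == 0))
  expect_true(all(res0$pvalue == 1))

  expect_error(differential_standin(cm, "D0", "D5_CM"), "replicates")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance (up to reordering)
  p <- c(0.001, 0.04, 0.2, 0.8, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("significance filter is boundary-inclusive and monotone", {
  res <- data.frame(
    comparison = "IMD_vs_D0",
    feature_id = paste0("f", 1:6),
    lfc = c(1.5, -1.5, 1.49, 4, 0.2, -2),
    pvalue = rep(0.001, 6),
    padj = c(0.05, 0.01, 0.01, 0.051, 0.04, 0.04))
  sig <- call_significant(res)
  expect_setequal(sig$feature_id, c("f1", "f2", "f6"))
  expect_equal(sig$direction[match(c("f1", "f2", "f6"), sig$feature_id)],
               c("up", "down", "down"))
  # relaxing thresholds never removes a feature
  sig2 <- call_significant(res, lfc_min = 1, padj_max = 0.1)
  expect_true(all(sig$feature_id %in% sig2$feature_id))
})

test_that("non-redundant union equals the brute-force set union", {
  sets <- list(a_vs_b = c("g2", "g1"), a_vs_c = c("g2", "g3"),
               b_vs_c = character(0))
  u <- nonredundant_union(sets)
  expect_equal(u, c("g1", "g2", "g3"))
  expect_length(u, 2 + 2 - 1)  # inclusion-exclusion
  expect_equal(nonredundant_union(list(x = character(0))), character(0))
  expect_error(nonredundant_union(setNames(sets, c("x", "x", "y"))),
               "uniquely named")

  # synthetic run against an independent union
  x <- tiny_sim()
  comps <- utils::head(pairwise_comparisons(), 4)
  sf <- size_factors(x$sim$rna)
  sig <- lapply(seq_len(nrow(comps)), function(i)
    call_significant(differential_standin(x$sim$rna, comps$a[i], comps$b[i],
                                          factors = sf)))
  names(sig) <- comps$label
  brute <- sort(unique(unlist(lapply(sig, `[[`, "feature_id"))))
  expect_equal(nonredundant_union(sig), brute)
})

test_that("differential tables round trip through TSV", {
  x <- tiny_sim()
  res <- differential_standin(x$sim$rna, "IMD", "D5_DM")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_diff_table(path)
  expect_equal(back$lfc, res$lfc)
  expect_equal(back$padj, res$padj)
})
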