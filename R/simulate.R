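#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults
#' emulate the explant study design: six conditions with 3 RNA and 2 ATAC
#' replicates, six expression and six accessibility archetype clusters,
#' 2,000 genes with 6,000 peaks on one 20 Mb chromosome, Gamma-Poisson
#' (negative binomial) count noise with a single shared dispersion, and a
#' planted expression/promoter-accessibility correlation of 0.6.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes,n_peaks Feature counts (`n_peaks >= n_genes`; each gene
#'   gets exactly one promoter peak within 1 kb of its TSS, the rest are
#'   distal distractors).
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param rna_replicates,atac_replicates Replicates per condition.
#' @param n_rna_clusters,n_atac_clusters Numbers of planted archetype
#'   clusters (defaults 6 and 6).
#' @param rna_archetypes,atac_archetypes Optional k x 6 matrices of
#'   per-cluster condition profiles (columns in [explant_conditions()]
#'   order); rows are standardized before use.  Defaults mimic the six
#'   published cluster shapes and require k = 6.
#' @param log2_amplitude Archetype amplitude in log2 units (default 2).
#' @param rna_log2_mean,atac_log2_mean Baseline log2 mean counts.
#' @param feature_log2_sd SD of per-feature baseline jitter (log2 units).
#' @param dispersion Shared negative-binomial dispersion (`size =
#'   1/dispersion`); `0` gives noiseless rounded means.
#' @param depth_factors `NULL` (sampled log-normally per sample with
#'   `depth_log_sd`) or a numeric vector/scalar of per-sample library-size
#'   multipliers.
#' @param depth_log_sd SD of log depth factors when sampled.
#' @param association_odds k x k matrix of enrichment odds for joint
#'   (RNA cluster, ATAC cluster) co-membership sampling; all entries
#'   positive.  Default: 5 on the diagonal, 1 elsewhere (a planted
#'   one-to-one association); all-ones gives the independence null.
#' @param rho Planted per-gene correlation between expression and promoter
#'   accessibility; scalar or length `n_genes`, in `[-1, 1]`.
#' @param coverage_noise Relative noise of the TSS coverage generator.
#' @param min_flank Minimum intergenic gap (bp, default 6000).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L, n_peaks = 6000L,
                       chrom_sizes = c(chr1 = 2e7),
                       rna_replicates = 3L, atac_replicates = 2L,
                       n_rna_clusters = 6L, n_atac_clusters = 6L,
                       rna_archetypes = NULL, atac_archetypes = NULL,
                       log2_amplitude = 2, rna_log2_mean = 7,
                       atac_log2_mean = 6, feature_log2_sd = 1,
                       dispersion = 0.05, depth_factors = NULL,
                       depth_log_sd = 0.2, association_odds = NULL,
                       rho = 0.6, coverage_noise = 0.1, min_flank = 6000L) {
  if (is.null(rna_archetypes)) {
    if (n_rna_clusters != 6L)
      stop_("default archetypes require 6 RNA clusters; supply rna_archetypes")
    rna_archetypes <- default_rna_archetypes()
  }
  if (is.null(atac_archetypes)) {
    if (n_atac_clusters != 6L)
      stop_("default archetypes require 6 ATAC clusters; supply atac_archetypes")
    atac_archetypes <- default_atac_archetypes()
  }
  if (is.null(association_odds)) {
    association_odds <- matrix(1, n_rna_clusters, n_atac_clusters)
    diag(association_odds) <- 5
  }
  if (any(association_odds <= 0)) stop_("association odds must be > 0")
  if (any(abs(rho) > 1)) stop_("|rho| must be <= 1")
  if (!(length(rho) %in% c(1L, n_genes)))
    stop_("rho must be scalar or length n_genes")
  if (is.null(names(chrom_sizes))) stop_("chrom_sizes must be named")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks), chrom_sizes = chrom_sizes,
              rna_replicates = as.integer(rna_replicates),
              atac_replicates = as.integer(atac_replicates),
              n_rna_clusters = as.integer(n_rna_clusters),
              n_atac_clusters = as.integer(n_atac_clusters),
              rna_archetypes = standardize_rows(rna_archetypes),
              atac_archetypes = standardize_rows(atac_archetypes),
              log2_amplitude = log2_amplitude,
              rna_log2_mean = rna_log2_mean, atac_log2_mean = atac_log2_mean,
              feature_log2_sd = feature_log2_sd, dispersion = dispersion,
              depth_factors = depth_factors, depth_log_sd = depth_log_sd,
              association_odds = association_odds, rho = rho,
              coverage_noise = coverage_noise,
              min_flank = as.integer(min_flank))
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments
#'   (`chrom_sizes` as a named map).
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$chrom_sizes)) cfg$chrom_sizes <- unlist(cfg$chrom_sizes)
  do.call(sim_config, cfg)
}

standardize_rows <- function(m) {
  t(apply(m, 1L, function(x) (x - mean(x)) / stats::sd(x)))
}

# Six condition profiles shaped like the published expression clusters:
# columns IMD, D0, D1_CM, D1_DM, D5_CM, D5_DM.
default_rna_archetypes <- function() {
  m <- rbind(
    C1 = c( 1.0, -1.0,  0.0,  0.0,  0.0,  1.0),  # high IMD & D5_DM, low D0
    C2 = c( 0.5,  0.0,  0.0,  1.0, -1.0,  0.5),  # high D1_DM, low D5_CM
    C3 = c( 1.5, -0.3, -0.3, -0.3, -0.3, -0.3),  # high IMD only
    C4 = c(-0.5, -0.5, -0.5,  1.0, -0.5,  1.0),  # up with vitreous
    C5 = c(-1.5,  0.3,  0.3,  0.3,  0.3,  0.3),  # low IMD, flat explanted
    C6 = c( 0.8,  0.3,  0.8, -1.1,  0.8, -1.1))  # high IMD/CM, low DM
  colnames(m) <- explant_conditions()
  m
}

default_atac_archetypes <- function() {
  m <- rbind(
    CA = c(-0.5,  1.0,  0.0, -0.5,  1.0, -1.0),  # open D0/D5_CM, closed DM
    CB = c( 0.5, -1.0,  0.0,  0.5, -1.0,  1.0),  # mirror of CA
    CC = c(-0.5, -0.5, -0.5,  0.0, -0.5,  1.5),  # most open D5_DM
    CD = c( 1.5,  0.0,  0.0, -0.5,  0.0, -1.5),  # open IMD, closed D5_DM
    CE = c(-1.5,  0.5,  0.0,  0.5,  0.0,  0.5),  # closed IMD
    CF = c(-0.5, -0.5,  1.5, -0.5,  0.0, -0.5))  # most open D1_CM
  colnames(m) <- explant_conditions()
  m
}

#' Simulate a toy gene annotation
#'
#' Places `n_genes` non-overlapping genes (both strands, 2-8 kb, 1-4
#' exons, 5'/3' UTRs) with at least `min_flank` bp between neighbours and
#' to the chromosome ends.  Deterministic under the config seed; rerunning
#' reproduces a byte-identical GTF.
#'
#' @param config A [sim_config()].
#' @param gtf_path Optional path; when given the annotation is also
#'   written with [write_gtf()].
#' @return A [gene_annotation()].
#' @export
simulate_annotation <- function(config, gtf_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0L) {
    ann <- structure(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer(), tss = integer(),
                         stringsAsFactors = FALSE),
      exons = cbind(empty_intervals(), rank = integer()),
      utr5 = empty_intervals(), utr3 = empty_intervals()),
      class = "gene_annotation")
    if (!is.null(gtf_path)) write_gtf(ann, gtf_path)
    return(ann)
  }
  sizes <- config$chrom_sizes
  quota <- largest_remainder(n, sizes / sum(sizes))
  genes <- list(); exons <- list(); u5 <- list(); u3 <- list()
  gid_i <- 0L
  for (ci in seq_along(sizes)) {
    q <- quota[ci]
    if (q == 0L) next
    len <- sample(2000:8000, q, replace = TRUE)
    need <- sum(len) + (q + 1L) * config$min_flank
    if (need > sizes[ci])
      stop_("infeasible packing on ", names(sizes)[ci],
            ": need ", need, " bp, have ", sizes[ci],
            "; increase chrom sizes or reduce n_genes")
    slack <- sizes[ci] - need
    u <- stats::runif(q + 1L)
    extra <- floor(slack * u / sum(u))
    gap <- config$min_flank + extra
    start <- cumsum(gap[seq_len(q)] + c(0L, len[-q])) + 1L
    strand <- sample(c("+", "-"), q, replace = TRUE)
    for (j in seq_len(q)) {
      gid_i <- gid_i + 1L
      gid <- sprintf("g%04d", gid_i)
      gs <- start[j]; ge <- gs + len[j] - 1L
      genes[[gid_i]] <- data.frame(gene_id = gid, chrom = names(sizes)[ci],
                                   strand = strand[j], start = gs, end = ge,
                                   stringsAsFactors = FALSE)
      str <- gene_structure(gs, ge, strand[j])
      str$exons$gene_id <- gid
      exons[[gid_i]] <- str$exons
      if (!is.null(str$utr5)) { str$utr5$gene_id <- gid; u5[[gid_i]] <- str$utr5 }
      if (!is.null(str$utr3)) { str$utr3$gene_id <- gid; u3[[gid_i]] <- str$utr3 }
    }
  }
  bindr <- function(l) if (length(l)) do.call(rbind, l) else empty_intervals()
  ann <- gene_annotation(do.call(rbind, genes), bindr(exons),
                         bindr(u5), bindr(u3))
  if (!is.null(gtf_path)) write_gtf(ann, gtf_path)
  ann
}

largest_remainder <- function(n, w) {
  exact <- n * w / sum(w)
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0L) {
    add <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# exon/intron partition of one gene span, with UTRs on the terminal exons
gene_structure <- function(gs, ge, strand) {
  L <- ge - gs + 1L
  ne <- sample(1:4, 1L)
  nparts <- 2L * ne - 1L
  u <- stats::runif(nparts)
  w <- 100L + floor((L - 100L * nparts) * u / sum(u))
  w[nparts] <- w[nparts] + (L - sum(w))
  ends <- gs - 1L + cumsum(w)
  starts <- c(gs, ends[-nparts] + 1L)
  exi <- seq(1L, nparts, by = 2L)
  ex <- data.frame(gene_id = NA_character_, start = starts[exi],
                   end = ends[exi], stringsAsFactors = FALSE)
  ex$rank <- if (strand == "+") seq_len(ne) else rev(seq_len(ne))
  first <- which(ex$rank == 1L); last <- which(ex$rank == ne)
  wid5 <- min(200L, ex$end[first] - ex$start[first] + 1L)
  wid3 <- min(300L, ex$end[last] - ex$start[last] + 1L)
  if (strand == "+") {
    utr5 <- data.frame(gene_id = NA_character_, start = ex$start[first],
                       end = ex$start[first] + wid5 - 1L)
    utr3 <- data.frame(gene_id = NA_character_, start = ex$end[last] - wid3 + 1L,
                       end = ex$end[last])
  } else {
    utr5 <- data.frame(gene_id = NA_character_, start = ex$end[first] - wid5 + 1L,
                       end = ex$end[first])
    utr3 <- data.frame(gene_id = NA_character_, start = ex$start[last],
                       end = ex$start[last] + wid3 - 1L)
  }
  list(exons = ex, utr5 = utr5, utr3 = utr3)
}

#' Simulate RNA and ATAC count matrices with planted structure
#'
#' Generates the full synthetic study: one promoter peak per gene (within
#' 1 kb of its TSS) plus distal distractor peaks; per-gene RNA cluster and
#' per-peak ATAC cluster labels drawn jointly from `association_odds`
#' (planting cluster association at the label level, so cross-table
#' analyses have exact ground truth); negative-binomial counts around
#' `depth x 2^(baseline + amplitude x archetype)`; and promoter-peak
#' accessibility sharing the gene's latent condition signal scaled by
#' `rho`, so expression and promoter accessibility correlate as planted.
#'
#' @param config A [sim_config()].
#' @param annotation A [gene_annotation()] from [simulate_annotation()]
#'   under the same config.
#' @return List with `rna` and `atac` ([count_matrix()]), `peaks`
#'   (data.frame as from [read_peaks()]) and `truth`: a list with
#'   `rna_cluster` (gene labels), `atac_cluster` (peak labels),
#'   `peak_gene` (intended promoter-peak assignment, `NA` for distal
#'   peaks), `promoter_peak` (gene -> peak id) and `rho` (per gene).
#' @export
simulate_counts <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "gene_annotation"))
  set.seed(config$seed + 1L)
  gn <- annotation$genes
  n <- nrow(gn)
  if (config$n_peaks < n) stop_("n_peaks must be >= n_genes")
  kr <- config$n_rna_clusters; ka <- config$n_atac_clusters
  rho <- rep_len(config$rho, n)

  # joint cluster labels from the association odds
  pr <- as.vector(t(config$association_odds))  # cell = (r-1)*ka + a
  cell <- sample.int(kr * ka, n, replace = TRUE, prob = pr / sum(pr))
  r_lab <- (cell - 1L) %/% ka + 1L
  a_lab <- (cell - 1L) %% ka + 1L

  # peaks: one promoter peak per gene, then distal distractors
  csize <- config$chrom_sizes
  pw <- sample(300:600, config$n_peaks, replace = TRUE)
  centre_p <- gn$tss + sample(-300:300, n, replace = TRUE)
  nd <- config$n_peaks - n
  centre_d <- integer(nd)
  chrom_d <- character(nd)
  if (nd > 0L) {
    tss_by_chrom <- split(gn$tss, gn$chrom)
    for (i in seq_len(nd)) {
      repeat {
        ch <- names(csize)[sample.int(length(csize), 1L,
                                      prob = csize / sum(csize))]
        pos <- sample.int(csize[[ch]] - 700L, 1L) + 350L
        tt <- tss_by_chrom[[ch]]
        if (is.null(tt) || all(abs(pos - tt) > 1500L)) break
      }
      centre_d[i] <- pos; chrom_d[i] <- ch
    }
  }
  centre <- c(centre_p, centre_d)
  chrom <- c(gn$chrom, chrom_d)
  start <- pmax(1L, centre - pw %/% 2L)
  peaks <- data.frame(peak_id = sprintf("peak%05d", seq_len(config$n_peaks)),
                      chrom = chrom, start = start, end = start + pw - 1L,
                      summit_offset = centre - start, summit = centre,
                      stringsAsFactors = FALSE)

  arch_r <- config$rna_archetypes   # standardized rows
  arch_a <- config$atac_archetypes
  amp <- config$log2_amplitude
  U <- arch_r[r_lab, , drop = FALSE]                       # n x 6
  # independent standardized per-gene profile; mixing it in at sqrt(1-rho^2)
  # makes the promoter peak share the gene's latent signal at exactly rho
  W <- standardize_rows(matrix(stats::rnorm(n * 6L), n, 6L))
  V <- rho * U + sqrt(1 - rho^2) * W                       # promoter signal

  rna_samples <- design_samples(config$rna_replicates, "r")
  atac_samples <- design_samples(config$atac_replicates, "a")
  depth <- function(ns) {
    if (is.null(config$depth_factors)) exp(stats::rnorm(ns, 0, config$depth_log_sd))
    else rep_len(config$depth_factors, ns)
  }
  d_rna <- depth(nrow(rna_samples)); d_atac <- depth(nrow(atac_samples))

  base_g <- stats::rnorm(n, config$rna_log2_mean, config$feature_log2_sd)
  rna_log2 <- base_g + amp * U                             # n x 6
  rna_counts <- draw_counts(rna_log2, rna_samples, d_rna, config$dispersion)
  rownames(rna_counts) <- gn$gene_id
  rna <- count_matrix(rna_counts, rna_samples$condition, rna_samples$replicate)

  base_p <- config$atac_log2_mean + rho * (base_g - config$rna_log2_mean) +
    sqrt(1 - rho^2) * stats::rnorm(n, 0, config$feature_log2_sd)
  a_d <- if (nd > 0L) sample.int(ka, nd, replace = TRUE) else integer(0)
  atac_log2 <- base_p + amp * V
  if (nd > 0L) {
    base_d <- stats::rnorm(nd, config$atac_log2_mean, config$feature_log2_sd)
    atac_log2 <- rbind(atac_log2, base_d + amp * arch_a[a_d, , drop = FALSE])
  }
  atac_counts <- draw_counts(atac_log2, atac_samples, d_atac, config$dispersion)
  rownames(atac_counts) <- peaks$peak_id
  atac <- count_matrix(atac_counts, atac_samples$condition,
                       atac_samples$replicate)

  truth <- list(
    rna_cluster = stats::setNames(r_lab, gn$gene_id),
    atac_cluster = stats::setNames(c(a_lab, a_d), peaks$peak_id),
    peak_gene = stats::setNames(c(gn$gene_id, rep(NA_character_, nd)),
                                peaks$peak_id),
    promoter_peak = stats::setNames(peaks$peak_id[seq_len(n)], gn$gene_id),
    rho = stats::setNames(rho, gn$gene_id))
  list(rna = rna, atac = atac, peaks = peaks, truth = truth)
}

design_samples <- function(reps, tag) {
  conds <- rep(explant_conditions(), each = reps)
  data.frame(sample_id = paste0(conds, "_", tag, rep(seq_len(reps),
                                                     times = 6L)),
             condition = conds, replicate = rep(seq_len(reps), times = 6L),
             stringsAsFactors = FALSE)
}

draw_counts <- function(log2mu, samples, depth, dispersion) {
  n <- nrow(log2mu)
  out <- matrix(0L, n, nrow(samples))
  colnames(out) <- samples$sample_id
  for (j in seq_len(nrow(samples))) {
    mu <- depth[j] * 2^log2mu[, match(samples$condition[j],
                                      explant_conditions())]
    out[, j] <- if (dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    else as.integer(round(mu))
  }
  out
}

#' Simulate TSS-centred accessibility coverage
#'
#' Per ATAC sample, a genes x bins matrix of accessibility signal in a
#' +/- 2 kb window around each TSS (10 bp bins, 401 bins with the centre
#' bin exactly on the TSS).  The profile is a Gaussian bump whose
#' amplitude is `log2(normalized expression + 1)` for the gene in that
#' sample's condition — a monotone function of expression — plus relative
#' Gaussian noise (`coverage_noise`); matrices are already oriented so
#' upstream of the TSS is on the left.
#'
#' @param config A [sim_config()].
#' @param annotation The simulated [gene_annotation()].
#' @param rna The simulated RNA [count_matrix()] (gene ids must match).
#' @return Object of class `tss_coverage`: list with `signal` (named list
#'   of matrices per sample), `positions` (bin centre offsets),
#'   `samples`, `gene_ids`.
#' @export
simulate_tss_coverage <- function(config, annotation, rna) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "gene_annotation"),
            inherits(rna, "count_matrix"))
  gene_ids <- annotation$genes$gene_id
  if (!all(gene_ids %in% rownames(rna$counts)))
    stop_("annotation and RNA matrix gene ids do not match")
  set.seed(config$seed + 2L)
  positions <- seq(-2000L, 2000L, by = 10L)
  shape <- exp(-positions^2 / (2 * 400^2))
  nm <- normalize_counts(rna)
  expr <- condition_means(nm$values[gene_ids, , drop = FALSE], nm$samples)
  amp <- log2(expr + 1)
  samples <- design_samples(config$atac_replicates, "a")
  signal <- list()
  for (j in seq_len(nrow(samples))) {
    a <- unname(amp[, samples$condition[j]])
    m <- outer(a, shape)
    if (config$coverage_noise > 0) {
      m <- m + config$coverage_noise * a *
        matrix(stats::rnorm(length(m)), nrow(m))
      m[m < 0] <- 0
    }
    rownames(m) <- gene_ids
    signal[[samples$sample_id[j]]] <- m
  }
  structure(list(signal = signal, positions = positions, samples = samples,
                 gene_ids = gene_ids),
            class = "tss_coverage")
}

#' @export
print.tss_coverage <- function(x, ...) {
  cat(sprintf("tss_coverage: %d genes x %d bins x %d samples\n",
              length(x$gene_ids), length(x$positions), length(x$signal)))
  invisible(x)
}

#' Simulate peak sequences with planted motif instances
#'
#' Generates one i.i.d. uniform A/C/G/T sequence per peak (peak width) and
#' plants exact consensus instances of the given PWMs: for each peak and
#' motif, with the configured probability the consensus (or its reverse
#' complement, each strand with probability 0.5) overwrites a uniformly
#' chosen window.  Deterministic under `seed`.
#'
#' @param peaks Peak data.frame (`peak_id`, `start`, `end`).
#' @param pwms A `pwm` or list of `pwm`s.
#' @param plant_prob Planting probability: scalar, per-peak vector, or
#'   peaks x motifs matrix.
#' @param seed Integer seed.
#' @return Named character vector of sequences (names = peak ids).
#' @export
simulate_sequences <- function(peaks, pwms, plant_prob = 0, seed = 1L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  widths <- peaks$end - peaks$start + 1L
  wmax <- max(vapply(pwms, function(p) ncol(p$matrix), integer(1L)))
  if (any(widths < wmax)) stop_("peak width smaller than motif length")
  np <- nrow(peaks); nm <- length(pwms)
  prob <- if (is.matrix(plant_prob)) plant_prob
          else matrix(rep_len(plant_prob, np), np, nm)
  set.seed(seed)
  seqs <- character(np)
  for (i in seq_len(np)) {
    s <- sample(c("A", "C", "G", "T"), widths[i], replace = TRUE)
    for (m in seq_len(nm)) {
      if (stats::runif(1L) < prob[i, m]) {
        cons <- strsplit(pwm_consensus(pwms[[m]]), "")[[1L]]
        if (stats::runif(1L) < 0.5)
          cons <- rev(c(A = "T", C = "G", G = "C", T = "A")[cons])
        at <- sample.int(widths[i] - length(cons) + 1L, 1L)
        s[at:(at + length(cons) - 1L)] <- cons
      }
    }
    seqs[i] <- paste0(s, collapse = "")
  }
  stats::setNames(seqs, peaks$peak_id)
}

#' Write ground-truth labels to TSV
#'
#' @param truth The `truth` element of [simulate_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(
    id = c(names(truth$rna_cluster), names(truth$atac_cluster)),
    kind = rep(c("gene", "peak"),
               c(length(truth$rna_cluster), length(truth$atac_cluster))),
    cluster = c(truth$rna_cluster, truth$atac_cluster),
    mapped_gene = c(rep(NA_character_, length(truth$rna_cluster)),
                    truth$peak_gene),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
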