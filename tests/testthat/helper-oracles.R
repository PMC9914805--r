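# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (per-element loops, no shared code with R/).

# Naive genomic annotation: for one peak anchor, scan every gene and every
# sub-feature explicitly and apply the category precedence ladder.
oracle_annotate_one <- function(anchor, chrom, ann,
                                bins = c(1000, 2000, 3000),
                                downstream = 300000) {
  cats <- peak_categories()
  gn <- ann$genes[ann$genes$chrom == chrom, ]
  if (!nrow(gn)) return(list(category = cats[11], gene = NA, dist = NA))
  d_abs <- abs(anchor - gn$tss)
  best <- min(d_abs)
  cand <- gn$gene_id[d_abs == best]
  gene <- sort(cand)[1]
  g <- gn[gn$gene_id == gene, ]
  dist <- if (g$strand == "+") anchor - g$tss else g$tss - anchor
  if (best <= bins[1]) return(list(category = cats[1], gene = gene, dist = dist))
  if (best <= bins[2]) return(list(category = cats[2], gene = gene, dist = dist))
  if (best <= bins[3]) return(list(category = cats[3], gene = gene, dist = dist))
  inside <- function(df) {
    for (i in seq_len(nrow(df))) {
      ch <- ann$genes$chrom[ann$genes$gene_id == df$gene_id[i]]
      if (ch == chrom && anchor >= df$start[i] && anchor <= df$end[i])
        return(TRUE)
    }
    FALSE
  }
  if (inside(ann$utr5)) return(list(category = cats[4], gene = gene, dist = dist))
  if (inside(ann$utr3)) return(list(category = cats[5], gene = gene, dist = dist))
  ex1 <- ann$exons[ann$exons$rank == 1, ]
  exo <- ann$exons[ann$exons$rank > 1, ]
  if (inside(ex1)) return(list(category = cats[6], gene = gene, dist = dist))
  if (inside(exo)) return(list(category = cats[7], gene = gene, dist = dist))
  # introns, rank in gene orientation
  in1 <- NULL; ino <- NULL
  for (gid in unique(ann$exons$gene_id)) {
    e <- ann$exons[ann$exons$gene_id == gid, ]
    e <- e[order(e$rank), ]
    if (nrow(e) < 2) next
    for (j in seq_len(nrow(e) - 1)) {
      s <- min(e$end[j], e$end[j + 1]) + 1
      en <- max(e$start[j], e$start[j + 1]) - 1
      row <- data.frame(gene_id = gid, start = s, end = en)
      if (j == 1) in1 <- rbind(in1, row) else ino <- rbind(ino, row)
    }
  }
  if (!is.null(in1) && inside(in1)) return(list(category = cats[8], gene = gene, dist = dist))
  if (!is.null(ino) && inside(ino)) return(list(category = cats[9], gene = gene, dist = dist))
  dn <- data.frame(
    gene_id = ann$genes$gene_id,
    start = ifelse(ann$genes$strand == "+", ann$genes$end + 1,
                   pmax(1, ann$genes$start - downstream)),
    end = ifelse(ann$genes$strand == "+", ann$genes$end + downstream,
                 ann$genes$start - 1))
  if (inside(dn)) return(list(category = cats[10], gene = gene, dist = dist))
  list(category = cats[11], gene = gene, dist = dist)
}

# Two-sided Fisher exact p by full enumeration over all tables with the
# observed margins: sum probabilities of tables no more probable.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- sapply(xs, function(x)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive PWM scan: loop every window on both strands, score base by base.
oracle_scan <- function(seq, pwm, score_fraction = 0.8) {
  mat <- log2(pwm$matrix / pwm$background)
  W <- ncol(mat)
  maxs <- sum(apply(mat, 2, max))
  thr <- score_fraction * maxs
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  sc1 <- function(chars) {
    s <- 0
    for (i in seq_along(chars)) {
      if (chars[i] %in% rownames(mat)) s <- s + mat[chars[i], i]
    }
    s
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- NULL
  for (st in seq_len(max(0, length(chars) - W + 1))) {
    win <- chars[st:(st + W - 1)]
    sf <- sc1(win)
    if (sf >= thr) hits <- rbind(hits, data.frame(start = st, strand = "+",
                                                  score = sf))
    sr <- sc1(rev(unname(comp[win])))
    if (sr >= thr) hits <- rbind(hits, data.frame(start = st, strand = "-",
                                                  score = sr))
  }
  hits
}

# Exact per-window tail probability that a uniform random window scores at
# or above the threshold: dynamic-programming convolution of the per-column
# log-odds score distribution.
oracle_window_tail <- function(pwm, score_fraction = 0.8, grid = 1e-4) {
  mat <- log2(pwm$matrix / pwm$background)
  thr <- score_fraction * sum(apply(mat, 2, max))
  scores <- c(0)
  probs <- c(1)
  for (i in seq_len(ncol(mat))) {
    scores <- as.vector(outer(scores, mat[, i], `+`))
    probs <- as.vector(outer(probs, rep(0.25, 4), `*`))
    key <- round(scores / grid)
    agg <- tapply(probs, key, sum)
    scores <- as.numeric(names(agg)) * grid
    probs <- as.vector(agg)
  }
  sum(probs[scores >= thr - 1e-9])
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# the published six-by-six gene cross-table (RNA clusters x ATAC clusters)
table1_counts <- function() {
  matrix(c(267, 157, 153, 227,  67,  37,
           300, 163, 129, 198, 107,  66,
           433, 198, 152, 417,  78,  91,
           395, 141, 236, 166, 269,  46,
           296,  96, 106, 124, 152,  36,
           487, 434, 217, 514, 119, 119),
         nrow = 6, byrow = TRUE,
         dimnames = list(paste0("C", 1:6), paste0("C", LETTERS[1:6])))
}

# label vectors realizing a given cross-table exactly
labels_from_table <- function(tab) {
  r <- integer(0); a <- integer(0)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    r <- c(r, rep(i, tab[i, j])); a <- c(a, rep(j, tab[i, j]))
  }
  ids <- sprintf("gene%05d", seq_along(r))
  list(rna = setNames(r, ids), atac = setNames(a, ids))
}

peak_at <- function(pos, id = "pk", chrom = "chr1") {
  data.frame(peak_id = id, chrom = chrom, start = pos - 50L, end = pos + 49L,
             summit_offset = 50L, summit = pos)
}

# a fixed length-10 motif with a sharp, non-palindromic consensus TTGACGTCTA
read_jaspar_fixture <- function() {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA9001 CREFIX",
    "A [ 2  1  1 40  1  1  1  1  1 40]",
    "C [ 1  1  1  1 40  1  1 40  1  1]",
    "G [ 1  1 40  1  1 40  1  1  1  1]",
    "T [40 40  1  1  1  1 40  1 40  1]"), path)
  on.exit(unlink(path))
  read_jaspar(path)[[1]]
}

# small shared simulated dataset for unit tests (fast: 120 genes)
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_genes = 120, n_peaks = 300,
                        chrom_sizes = c(chr1 = 2.5e6))
      ann <- simulate_annotation(cfg)
      sim <- simulate_counts(cfg, ann)
      cache <<- list(cfg = cfg, ann = ann, sim = sim)
    }
    cache
  }
})
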