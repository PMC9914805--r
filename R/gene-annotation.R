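#' Gene annotation container
#'
#' Holds gene models on a (toy or real) genome: per-gene coordinates, strand
#' and TSS plus exon and UTR sub-features.  All coordinates are 1-based
#' inclusive (the convention of GTF and of the IRanges stack used
#' internally); BED-style inputs are converted at the parse boundary.
#'
#' The TSS is defined at gene level on the union transcript span:
#' `start` on the `+` strand, `end` on the `-` strand.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive).
#' @param exons data.frame with columns `gene_id`, `start`, `end`, `rank`
#'   (exon number in 5'->3' gene orientation).  Every gene must have at
#'   least one exon nested within its span; exons of a gene must not
#'   overlap.
#' @param utr5,utr3 Optional data.frames with columns `gene_id`, `start`,
#'   `end`.
#' @return An object of class `gene_annotation` with elements `genes`
#'   (gains a computed `tss` column), `exons`, `utr5`, `utr3`.
#' @export
gene_annotation <- function(genes, exons,
                            utr5 = empty_intervals(), utr3 = empty_intervals()) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(genes))) stop_("'genes' needs columns: ",
                                          paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop_("duplicate gene_id")
  if (!all(genes$strand %in% c("+", "-"))) stop_("strand must be '+' or '-'")
  if (any(genes$start > genes$end)) stop_("gene start > end")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)

  for (nm in c("exons", "utr5", "utr3")) {
    df <- get(nm)
    if (nrow(df)) {
      if (!all(df$gene_id %in% genes$gene_id))
        stop_(nm, " refers to unknown gene_id")
      span <- genes[match(df$gene_id, genes$gene_id), ]
      if (any(df$start < span$start | df$end > span$end | df$start > df$end))
        stop_(nm, " intervals must nest within the gene span")
    }
  }
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex)) stop_("gene(s) without exons: ",
                                paste(missing_ex, collapse = ", "))
  # non-overlap within gene
  for (g in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == g, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop_("overlapping exons in gene ", g)
  }
  if (!"rank" %in% names(exons)) {
    exons <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
      st <- genes$strand[match(e$gene_id[1L], genes$gene_id)]
      e <- e[order(e$start, decreasing = (st == "-")), ]
      e$rank <- seq_len(nrow(e))
      e
    }))
    rownames(exons) <- NULL
  }
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_annotation")
}

empty_intervals <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' @export
length.gene_annotation <- function(x) nrow(x$genes)

#' Read gene models from a GTF file
#'
#' Parses a GTF (GTF2.2 attribute dialect) into a [gene_annotation()].
#' Gene models are assembled per `gene_id` from `gene`/`transcript`/`exon`
#' and UTR feature lines (`five_prime_utr`/`three_prime_utr`, with `5UTR`/
#' `3UTR` accepted as synonyms).  Exons from multiple transcripts of a gene
#' are collapsed to their union.  A gene with no exon lines raises a warning
#' and its transcript (or gene) span is used as a single exon.
#'
#' @param path GTF file path.
#' @return A [gene_annotation()] object (1-based inclusive coordinates, as
#'   in the file).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf < 9L))
    stop_("malformed GTF line ", which(keep)[which(nf < 9L)[1L]],
          ": fewer than 9 tab-delimited fields")
  gr <- rtracklayer::import(path, format = "gtf")
  typ <- as.character(gr$type)
  gid <- gr$gene_id
  if (is.null(gid) || anyNA(gid))
    stop_("GTF records missing gene_id attribute")

  take <- function(types) {
    i <- typ %in% types
    data.frame(gene_id = gid[i],
               chrom = as.character(GenomicRanges::seqnames(gr)[i]),
               strand = as.character(GenomicRanges::strand(gr)[i]),
               start = GenomicRanges::start(gr)[i],
               end = GenomicRanges::end(gr)[i],
               stringsAsFactors = FALSE)
  }
  gn <- take("gene")
  tx <- take("transcript")
  ex <- take("exon")
  u5 <- take(c("five_prime_utr", "5UTR"))
  u3 <- take(c("three_prime_utr", "3UTR"))

  if (!nrow(gn)) {  # no explicit gene lines: derive spans from transcripts/exons
    src <- if (nrow(tx)) tx else ex
    if (!nrow(src)) stop_("GTF contains no gene, transcript or exon records")
    gn <- do.call(rbind, lapply(split(src, src$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
                 strand = d$strand[1L], start = min(d$start), end = max(d$end),
                 stringsAsFactors = FALSE)))
  }
  no_ex <- setdiff(gn$gene_id, ex$gene_id)
  if (length(no_ex)) {
    warning("gene(s) without exon records, using transcript span as single exon: ",
            paste(no_ex, collapse = ", "), call. = FALSE)
    src <- rbind(tx[tx$gene_id %in% no_ex, ], gn[gn$gene_id %in% no_ex, ])
    add <- do.call(rbind, lapply(split(src, src$gene_id), function(d)
      d[which.max(d$end - d$start), ]))
    ex <- rbind(ex, add)
  }
  ex <- collapse_union(ex)
  u5 <- collapse_union(u5)
  u3 <- collapse_union(u3)
  gn <- gn[order(gn$gene_id), ]
  rownames(gn) <- NULL
  gene_annotation(gn, ex, u5, u3)
}

# union of possibly duplicated/overlapping per-gene intervals
collapse_union <- function(df) {
  if (!nrow(df)) return(empty_intervals())
  out <- lapply(split(df, df$gene_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(gene_id = d$gene_id[1L], start = IRanges::start(ir),
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a gene annotation to GTF
#'
#' Emits `gene`, `transcript`, `exon`, `five_prime_utr` and
#' `three_prime_utr` lines (one transcript per gene, the union span), with
#' GTF2.2 attributes.  [read_gtf()] of the output reproduces the input
#' annotation exactly.
#'
#' @param annotation A [gene_annotation()].
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, source = "crosspeak") {
  gn <- annotation$genes
  fmt <- function(chrom, type, start, end, strand, gid, extra = "") {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";%s",
            chrom, source, type, start, end, strand, gid, gid, extra)
  }
  lines <- character(0)
  for (i in seq_len(nrow(gn))) {
    g <- gn[i, ]
    lines <- c(lines,
               fmt(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id),
               fmt(g$chrom, "transcript", g$start, g$end, g$strand, g$gene_id))
    for (nm in c("exons", "utr5", "utr3")) {
      d <- annotation[[nm]]
      d <- d[d$gene_id == g$gene_id, , drop = FALSE]
      if (!nrow(d)) next
      type <- c(exons = "exon", utr5 = "five_prime_utr",
                utr3 = "three_prime_utr")[[nm]]
      d <- d[order(d$start, decreasing = (g$strand == "-")), ]
      for (j in seq_len(nrow(d))) {
        extra <- if (type == "exon") sprintf(" exon_number \"%d\";", j) else ""
        lines <- c(lines, fmt(g$chrom, type, d$start[j], d$end[j], g$strand,
                              g$gene_id, extra))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
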