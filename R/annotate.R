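#' The eleven genomic feature categories
#'
#' Category labels, in precedence order, used by [annotate_peaks()]:
#' three promoter distance bins from the TSS, first/other exon,
#' first/other intron, the two UTRs, a downstream window (default 300 kb
#' past the gene 3' end) and distal intergenic.
#'
#' @return Character vector of length 11.
#' @export
peak_categories <- function() {
  c("Promoter\u22641kb", "Promoter1\u20132kb", "Promoter2\u20133kb",
    "UTR5", "UTR3", "FirstExon", "OtherExon", "FirstIntron", "OtherIntron",
    "Downstream\u2264300kb", "DistalIntergenic")
}

#' Annotate peaks with genomic feature categories and nearest genes
#'
#' Assigns each peak exactly one of the eleven categories of
#' [peak_categories()] and its nearest gene.  The anchor point is the peak
#' summit when present, else the interval midpoint.  The nearest gene is
#' the gene minimizing the absolute anchor-to-TSS distance (ties broken by
#' lexicographically smaller `gene_id`); `tss_distance` is signed in gene
#' orientation, negative upstream of the TSS.
#'
#' Categories are decided by a precedence ladder: promoter distance bins
#' (by `|tss_distance|`, boundaries inclusive on the outer edge) beat
#' 5' UTR, then 3' UTR, first exon, other exon, first intron, other
#' intron, the downstream window, and finally distal intergenic.
#' Containment categories consider the sub-features of *all* genes, not
#' just the nearest one.  A peak on a chromosome absent from the
#' annotation is `DistalIntergenic` with `nearest_gene = NA` (tallied in
#' the `n_off_annotation` attribute).
#'
#' @param peaks data.frame as from [read_peaks()] (columns `peak_id`,
#'   `chrom`, `start`, `end`, optionally `summit`).
#' @param annotation A [gene_annotation()].
#' @param promoter_bins Outer edges (bp) of the three promoter bins
#'   (default `c(1000, 2000, 3000)`).
#' @param downstream_window Extent (bp) of the downstream category past the
#'   gene 3' end.  The printed convention of the source analyses is 300 kb;
#'   some annotators default to 300 bp - hence a knob.
#' @return data.frame with columns `peak_id`, `category` (factor with the
#'   eleven levels), `nearest_gene`, `tss_distance`.
#' @export
annotate_peaks <- function(peaks, annotation,
                           promoter_bins = c(1000L, 2000L, 3000L),
                           downstream_window = 300000L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  cats <- peak_categories()
  n <- nrow(peaks)
  anchor <- if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L, peaks$summit)
  } else (peaks$start + peaks$end) %/% 2L

  gn <- annotation$genes
  nearest_gene <- rep(NA_character_, n)
  tss_distance <- rep(NA_integer_, n)
  on_ann <- peaks$chrom %in% gn$chrom

  for (ch in unique(peaks$chrom[on_ann])) {
    gi <- which(gn$chrom == ch)
    pi <- which(peaks$chrom == ch)
    ord <- order(gn$tss[gi], gn$gene_id[gi])
    stss <- gn$tss[gi][ord]
    sgid <- gn$gene_id[gi][ord]
    sstr <- gn$strand[gi][ord]
    # lexicographically smallest gene id per run of equal TSS values
    run_best <- stats::ave(seq_along(stss), stss, FUN = function(ix) ix[1L])
    a <- anchor[pi]
    fi <- findInterval(a, stss)
    dl <- ifelse(fi >= 1L, a - stss[pmax(fi, 1L)], Inf)
    dr <- ifelse(fi < length(stss), stss[pmin(fi + 1L, length(stss))] - a, Inf)
    use_left <- dl < dr | (dl == dr &
      sgid[run_best[pmax(fi, 1L)]] <= sgid[run_best[pmin(fi + 1L, length(stss))]])
    idx <- ifelse(use_left, run_best[pmax(fi, 1L)],
                  run_best[pmin(fi + 1L, length(stss))])
    nearest_gene[pi] <- sgid[idx]
    d <- a - stss[idx]
    tss_distance[pi] <- ifelse(sstr[idx] == "+", d, -d)
  }

  category <- rep(cats[11L], n)  # DistalIntergenic default
  absd <- abs(tss_distance)
  category[on_ann & absd <= promoter_bins[1L]] <- cats[1L]
  category[on_ann & absd > promoter_bins[1L] & absd <= promoter_bins[2L]] <- cats[2L]
  category[on_ann & absd > promoter_bins[2L] & absd <= promoter_bins[3L]] <- cats[3L]

  undecided <- on_ann & absd > promoter_bins[3L]
  agr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(anchor, width = 1L))
  hit_any <- function(df) {
    if (!nrow(df)) return(logical(n))
    ch <- gn$chrom[match(df$gene_id, gn$gene_id)]
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(df$start, df$end))
    ov <- GenomicRanges::findOverlaps(agr, gr)
    out <- logical(n)
    out[unique(S4Vectors::queryHits(ov))] <- TRUE
    out
  }
  ex <- annotation$exons
  ladder <- list(
    UTR5 = annotation$utr5,
    UTR3 = annotation$utr3,
    FirstExon = ex[ex$rank == 1L, , drop = FALSE],
    OtherExon = ex[ex$rank > 1L, , drop = FALSE],
    FirstIntron = gene_introns(annotation, first_only = TRUE),
    OtherIntron = gene_introns(annotation, first_only = FALSE),
    Downstream = downstream_windows(annotation, downstream_window))
  lad_cat <- c(cats[4L], cats[5L], cats[6L], cats[7L], cats[8L], cats[9L], cats[10L])
  for (j in seq_along(ladder)) {
    if (!any(undecided)) break
    hit <- hit_any(ladder[[j]])
    take <- undecided & hit
    category[take] <- lad_cat[j]
    undecided <- undecided & !hit
  }

  n_off <- sum(!on_ann)
  if (n_off) message(n_off, " peak(s) on chromosomes absent from the annotation")
  out <- data.frame(peak_id = peaks$peak_id,
                    category = factor(category, levels = cats),
                    nearest_gene = nearest_gene,
                    tss_distance = tss_distance,
                    stringsAsFactors = FALSE)
  attr(out, "n_off_annotation") <- n_off
  out
}

# Intron intervals; rank counted in gene orientation.  first_only selects
# the intron between exon ranks 1 and 2 (TRUE) or all later introns (FALSE).
gene_introns <- function(annotation, first_only) {
  ex <- annotation$exons
  out <- lapply(split(ex, ex$gene_id), function(e) {
    if (nrow(e) < 2L) return(NULL)
    e <- e[order(e$rank), ]
    # consecutive ranks j, j+1; genomic interval between them
    s <- pmin(e$end[-nrow(e)], e$end[-1L]) + 1L
    en <- pmax(e$start[-nrow(e)], e$start[-1L]) - 1L
    keep <- if (first_only) 1L else setdiff(seq_len(nrow(e) - 1L), 1L)
    if (!length(keep)) return(NULL)
    data.frame(gene_id = e$gene_id[1L], start = s[keep], end = en[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_intervals() else out[out$start <= out$end, , drop = FALSE]
}

downstream_windows <- function(annotation, window) {
  gn <- annotation$genes
  if (!nrow(gn)) return(empty_intervals())
  data.frame(gene_id = gn$gene_id,
             start = ifelse(gn$strand == "+", gn$end + 1L,
                            pmax(1L, gn$start - window)),
             end = ifelse(gn$strand == "+", gn$end + window, gn$start - 1L),
             stringsAsFactors = FALSE)
}

#' Category percentages of an annotated peak set
#'
#' @param records data.frame from [annotate_peaks()].
#' @return Named numeric vector over the eleven categories, summing to 100.
#' @export
feature_distribution <- function(records) {
  if (!nrow(records)) stop_("no annotation records")
  tab <- table(factor(records$category, levels = peak_categories()))
  stats::setNames(100 * as.vector(tab) / nrow(records), names(tab))
}

#' Promoter vs non-promoter split of DAR sets, with fold ratios
#'
#' Counts, for each differentially accessible region (DAR) set, how many
#' regions fall in a promoter category (any of the three promoter bins)
#' versus elsewhere, and optionally the fold ratio of those counts between
#' paired sets (e.g. day 5 over day 1 for each medium), rounded to one
#' decimal.  A fold with a zero denominator is reported as `NA`
#' (undefined), never infinity.
#'
#' @param dar_sets Named list; each element a character vector of peak ids
#'   or a data.frame with a `feature_id` column.
#' @param records Annotation data.frame from [annotate_peaks()] covering
#'   the peaks.
#' @param pairs Optional data.frame with columns `earlier` and `later`
#'   naming elements of `dar_sets` to form fold ratios `later / earlier`.
#' @return List with `counts` (data.frame `set`, `n_promoter`,
#'   `n_nonpromoter`) and `folds` (data.frame `earlier`, `later`,
#'   `promoter_fold`, `nonpromoter_fold`; `NULL` when `pairs` is absent).
#' @export
promoter_split_summary <- function(dar_sets, records, pairs = NULL) {
  if (is.null(names(dar_sets)) || anyDuplicated(names(dar_sets)))
    stop_("'dar_sets' must be uniquely named")
  prom <- peak_categories()[1:3]
  is_prom <- stats::setNames(records$category %in% prom, records$peak_id)
  counts <- do.call(rbind, lapply(names(dar_sets), function(nm) {
    ids <- dar_sets[[nm]]
    if (is.data.frame(ids)) ids <- ids$feature_id
    miss <- setdiff(ids, records$peak_id)
    if (length(miss)) stop_("set ", nm, ": peak(s) missing from records")
    p <- sum(is_prom[ids])
    data.frame(set = nm, n_promoter = p, n_nonpromoter = length(ids) - p,
               stringsAsFactors = FALSE)
  }))
  folds <- NULL
  if (!is.null(pairs)) {
    fold1 <- function(earlier, later)
      ifelse(earlier == 0, NA_real_, round(later / earlier, 1L))
    ce <- counts[match(pairs$earlier, counts$set), ]
    cl <- counts[match(pairs$later, counts$set), ]
    folds <- data.frame(earlier = pairs$earlier, later = pairs$later,
                        promoter_fold = fold1(ce$n_promoter, cl$n_promoter),
                        nonpromoter_fold = fold1(ce$n_nonpromoter, cl$n_nonpromoter),
                        stringsAsFactors = FALSE)
  }
  list(counts = counts, folds = folds)
}
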