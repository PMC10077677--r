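#' Construct a set of genomic intervals
#'
#' Intervals follow the BED convention used throughout the package:
#' 0-based, half-open `[start, end)`. Every downstream stage (differential
#' enhancer calling, motif scanning, orthology mapping) consumes and emits
#' this representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector of 0-based inclusive start offsets.
#' @param end integer vector of exclusive end offsets; `end > start`.
#' @param name optional identifiers (recycled `NA` if missing).
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"` (unspecified).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, of class `genomic_intervals`.
#' @examples
#' genomic_intervals("chr1", c(100L, 500L), c(200L, 900L))
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (is.null(name)) name <- rep_len(NA_character_, n)
  if (is.null(strand)) strand <- rep_len("*", n)
  strand <- rep_len(as.character(strand), n)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = rep_len(as.character(name), n),
                   strand = strand, stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("chrom must be non-empty")
  if (any(df$start < 0)) stop("start must be >= 0")
  if (any(df$end <= df$start)) stop("end must be > start")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(df)
}

#' Construct a gene model table
#'
#' One record per gene: a single TSS per gene (isoform-aware TSS selection is
#' out of scope) and an optional ortholog identifier pointing into the other
#' species' gene namespace.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tss 0-based transcription start offsets.
#' @param ortholog_id optional counterpart gene ids in the other species.
#' @return A `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, ortholog_id = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  tss <- as.integer(tss)
  if (any(tss < 0)) stop("tss must be >= 0")
  if (is.null(ortholog_id)) ortholog_id <- rep_len(NA_character_, n)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = rep_len(as.character(chrom), n),
                   strand = rep_len(as.character(strand), n),
                   tss = tss,
                   ortholog_id = rep_len(as.character(ortholog_id), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Annotation set
#'
#' A labelled collection of intervals (e.g. ENCODE cCRE-ELS elements, TF
#' peaks) kept sorted by `(chrom, start)`. Overlapping annotations are
#' allowed.
#'
#' @param intervals interval `data.frame` (see [genomic_intervals()]).
#' @param label free-text label for the set.
#' @return The sorted interval `data.frame` with a `label` attribute, class
#'   `annotation_set`.
#' @export
annotation_set <- function(intervals, label = "") {
  validate_intervals(intervals)
  ord <- order(intervals$chrom, intervals$start)
  out <- intervals[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- unique(c("annotation_set", class(out)))
  out
}

#' Interval midpoints
#'
#' @param regions interval data.frame.
#' @return Integer midpoints, `floor((start + end) / 2)`.
#' @export
interval_midpoint <- function(regions) {
  as.integer(floor((regions$start + regions$end) / 2))
}

#' Nearest gene to a genomic interval
#'
#' Finds, for each query region, the gene whose TSS is closest to the region
#' midpoint, considering only genes on the same chromosome. This is the
#' IRE-to-gene linking rule: each enhancer is associated with its nearest
#' gene. Distance is `|tss - midpoint|`, reported as 0 when the TSS falls
#' inside the region. Ties are broken by the smaller TSS coordinate, then by
#' lexicographic `gene_id`.
#'
#' @param queries interval data.frame (one or more regions).
#' @param genes gene model data.frame (see [gene_models()]).
#' @return A data.frame with one row per query: `gene_id`, `distance`
#'   (non-negative), and `signed_offset` (`tss - midpoint`). Queries with no
#'   gene on their chromosome get `NA` in all columns (flagged unlinked, not
#'   dropped).
#' @export
nearest_feature <- function(queries, genes) {
  if (nrow(genes) == 0) stop("no features")
  mid <- interval_midpoint(queries)
  n <- nrow(queries)
  out <- data.frame(gene_id = rep_len(NA_character_, n),
                    distance = rep_len(NA_real_, n),
                    signed_offset = rep_len(NA_real_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == queries$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- abs(g$tss - mid[i])
    ord <- order(d, g$tss, g$gene_id)
    best <- g[ord[1L], ]
    inside <- best$tss >= queries$start[i] && best$tss < queries$end[i]
    out$gene_id[i] <- best$gene_id
    out$distance[i] <- if (inside) 0 else abs(best$tss - mid[i])
    out$signed_offset[i] <- best$tss - mid[i]
  }
  out
}

#' Genes with a TSS within a window of an interval midpoint
#'
#' Implements the "genes located within 100 kb from IREs" linking rule: a
#' gene qualifies when its TSS lies in the closed window
#' `[midpoint - window, midpoint + window]` (a TSS exactly at the bound is
#' included).
#'
#' @param query a single-region interval data.frame (first row used).
#' @param genes gene model data.frame.
#' @param window half-width in bp, `> 0`.
#' @return The qualifying subset of `genes` (possibly empty).
#' @export
features_within <- function(query, genes, window) {
  if (window < 0) stop("window must be non-negative")
  mid <- interval_midpoint(query)[1L]
  keep <- genes$chrom == query$chrom[1L] &
    genes$tss >= mid - window & genes$tss <= mid + window
  genes[keep, , drop = FALSE]
}

#' Remove promoter-proximal peaks
#'
#' Drops every peak whose midpoint falls within `tss - flank` to
#' `tss + flank` (closed) of any gene's TSS; the remainder are candidate
#' distal enhancers. The default 2 kb flank reproduces the promoter
#' definition used when depleting promoter peaks before enhancer calling.
#' Promoter assignment uses the peak midpoint. Idempotent; with no genes
#' supplied all peaks are kept.
#'
#' @param peaks interval data.frame.
#' @param genes gene model data.frame.
#' @param flank promoter half-width in bp (default 2000).
#' @return The distal subset of `peaks`, input order preserved.
#' @export
exclude_promoter_proximal <- function(peaks, genes, flank = 2000) {
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(peaks)
  keep <- !promoter_proximal(peaks, genes, flank)
  peaks[keep, , drop = FALSE]
}

promoter_proximal <- function(peaks, genes, flank = 2000) {
  mid <- interval_midpoint(peaks)
  prox <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    tss <- genes$tss[genes$chrom == ch]
    if (length(tss) == 0) next
    for (i in idx) prox[i] <- any(abs(tss - mid[i]) <= flank)
  }
  prox
}

#' Overlap test against an annotation set
#'
#' For each query, reports whether it overlaps at least `min_overlap` bases
#' of any annotation, under half-open interval arithmetic (adjacent
#' intervals do not overlap). Used e.g. to ask which inactive IREs fall in
#' cCRE enhancer-like elements, and for the peak-overlap counts of the
#' relative-overlap-ratio statistic.
#'
#' @param queries interval data.frame.
#' @param annotations interval data.frame (see [annotation_set()]).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return Logical vector, one entry per query.
#' @export
intersect_any <- function(queries, annotations, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  n <- nrow(queries)
  if (n == 0) return(logical(0))
  if (is.null(annotations) || nrow(annotations) == 0) return(logical(n))
  hit <- logical(n)
  for (ch in unique(queries$chrom)) {
    qi <- which(queries$chrom == ch)
    ann <- annotations[annotations$chrom == ch, , drop = FALSE]
    if (nrow(ann) == 0) next
    q <- IRanges::IRanges(start = queries$start[qi] + 1L, end = queries$end[qi])
    s <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
    ov <- IRanges::findOverlaps(q, s, minoverlap = min_overlap)
    hit[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}
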