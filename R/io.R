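# File interfaces: BED4/BED6, GTF gene records, ortholog tables, count
# matrices, and the scRNA MTX trio. All region coordinates on disk are BED
# (0-based half-open); GTF (1-based inclusive) is converted on read.

#' Read a BED4/BED6 file
#'
#' @param path tab-separated BED file without header.
#' @return A `genomic_intervals` data.frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  genomic_intervals(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    name = if (ncol(df) >= 4) df[[4]] else NULL,
                    strand = if (ncol(df) >= 6) df[[6]] else NULL)
}

#' Write intervals as BED
#'
#' Emits BED4 (or BED6 when any strand is specified); scores are written as
#' `.`.
#'
#' @param regions interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  nm <- ifelse(is.na(regions$name), ".", regions$name)
  if (!is.null(regions$strand) && any(regions$strand != "*")) {
    lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s", regions$chrom, regions$start,
                     regions$end, nm, ifelse(regions$strand == "*", ".",
                                             regions$strand))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, nm)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Extracts gene-level records (or collapses transcript/exon records to one
#' span per `gene_id`) and derives the TSS by strand: plus-strand TSS is the
#' record start, minus-strand TSS the record end. Coordinates are converted
#' from GTF 1-based inclusive to the package's 0-based convention.
#'
#' @param path GTF file.
#' @return A `gene_models` data.frame.
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  gid <- as.character(md$gene_id)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start1 <- GenomicRanges::start(gr)  # 1-based
  end1 <- GenomicRanges::end(gr)
  # collapse to one record per gene: min start / max end over its features
  sp <- split(seq_along(gid), gid)
  first <- vapply(sp, `[`, integer(1), 1L)
  gstart <- vapply(sp, function(i) min(start1[i]), numeric(1))
  gend <- vapply(sp, function(i) max(end1[i]), numeric(1))
  gstrand <- strand[first]
  tss0 <- ifelse(gstrand == "-", gend - 1, gstart - 1)  # 0-based offset
  gene_models(gene_id = names(sp), chrom = chrom[first],
              strand = ifelse(gstrand %in% c("+", "-"), gstrand, "+"),
              tss = tss0)
}

#' Write gene models as a minimal GTF
#'
#' One `gene` feature line per gene; the gene span is written as a 1 bp
#' feature at the TSS unless `start`/`end` columns are present.
#'
#' @param genes gene model data.frame.
#' @param path output path.
#' @param source source field (default "irekit").
#' @export
write_gene_models_gtf <- function(genes, path, source = "irekit") {
  if (all(c("start", "end") %in% names(genes))) {
    s1 <- genes$start + 1L
    e1 <- genes$end
  } else {
    s1 <- genes$tss + 1L
    e1 <- genes$tss + 1L
  }
  lines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   genes$chrom, source, s1, e1, genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog table
#'
#' @param path TSV with header columns `query_gene_id`, `target_gene_id`,
#'   `pct_identity`.
#' @return A data.frame with those columns.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("query_gene_id", "target_gene_id", "pct_identity")
                %in% names(df)))
  df
}

#' Write an ortholog table
#' @param orthologs data.frame with `query_gene_id`, `target_gene_id`,
#'   `pct_identity`.
#' @param path output TSV path.
#' @export
write_ortholog_table <- function(orthologs, path) {
  utils::write.table(orthologs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV
#'
#' Rows are features (regions or genes, taken from the first column), columns
#' samples (header row).
#'
#' @param path TSV path.
#' @return Integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a count matrix TSV
#' @param mat matrix with rownames and colnames.
#' @param path output path.
#' @param feature_col name of the first (feature id) column.
#' @export
write_count_matrix <- function(mat, path, feature_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an scRNA count matrix (MTX trio)
#'
#' @param mtx_path MatrixMarket sparse counts (genes x cells).
#' @param genes_path TSV of gene ids (one per row, no header).
#' @param cells_path TSV with header `cell_id`, `type`, `condition`.
#' @return List with `counts` (sparse dgCMatrix, gene rownames, cell
#'   colnames) and `cell_meta` data.frame.
#' @export
read_sc_matrix <- function(mtx_path, genes_path, cells_path) {
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- utils::read.table(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  rownames(counts) <- genes
  colnames(counts) <- cells$cell_id
  list(counts = counts, cell_meta = cells)
}

#' Write an scRNA count matrix (MTX trio)
#' @param counts genes x cells matrix (dense or sparse).
#' @param cell_meta data.frame with `cell_id`, `type`, `condition`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_sc_matrix <- function(counts, cell_meta, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"), mtx)
  genes <- file.path(dir, "genes.tsv")
  writeLines(rownames(counts), genes)
  cells <- file.path(dir, "cells.tsv")
  utils::write.table(cell_meta, cells, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mtx = mtx, genes = genes, cells = cells))
}

#' Extract region sequences from a genome
#'
#' @param regions interval data.frame.
#' @param genome named `Biostrings::DNAStringSet` or named character vector
#'   of chromosome sequences.
#' @return Character vector of uppercase sequences, one per region.
#' @export
region_sequences <- function(regions, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
    if (regions$end[i] > nchar(genome[[ch]]))
      stop("region beyond chromosome bound: ", ch)
    out[i] <- substr(genome[[ch]], regions$start[i] + 1L, regions$end[i])
  }
  toupper(out)
}
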