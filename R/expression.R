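# TPM quantification, simplified differential expression, and the
# single-cell cell-type assignment of induced genes.

#' Transcripts per million
#'
#' `TPM_i = 1e6 * (q_i / l_i) / sum_j(q_j / l_j)`: counts are first
#' length-normalized, then scaled so every sample sums to one million.
#'
#' @param counts per-gene read counts (vector or genes x samples matrix).
#' @param lengths per-gene transcript lengths in bp (union-exon lengths for
#'   gene-level counts); must be positive for genes with counts.
#' @return TPM values with the same shape as `counts`; each column sums to
#'   `1e6`.
#' @export
tpm <- function(counts, lengths) {
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == length(lengths))
    return(apply(counts, 2, tpm, lengths = lengths))
  }
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0 & counts > 0)) stop("length must be > 0 for quantified genes")
  rate <- ifelse(lengths > 0, counts / lengths, 0)
  denom <- sum(rate)
  if (denom == 0) stop("empty library")
  1e6 * rate / denom
}

# median-of-ratios size factors (reference = per-gene geometric mean over
# samples; genes with any zero are ignored)
median_of_ratios <- function(counts) {
  lg <- log(counts)
  ok <- apply(is.finite(lg), 1, all)
  if (!any(ok)) return(colSums(counts) / mean(colSums(counts)))
  ref <- rowMeans(lg[ok, , drop = FALSE])
  sf <- apply(lg[ok, , drop = FALSE], 2, function(col) {
    exp(stats::median(col - ref))
  })
  sf / exp(mean(log(sf)))
}

#' Simplified differential gene expression
#'
#' A deliberately compact differential-expression procedure:
#' median-of-ratios size factors, pseudocounted log2 fold changes of
#' normalized condition means, a two-group negative-binomial exact-style
#' test with a common method-of-moments dispersion, and BH FDR. The
#' significance rule used downstream for selecting induced IRE-associated
#' genes is fold change > 1.5 at FDR < 0.1.
#'
#' @param counts genes x samples integer matrix (rownames = gene ids).
#' @param condition per-sample labels, `"injured"` or `"control"`.
#' @param fc_threshold,alpha,criterion significance rule (defaults 1.5,
#'   0.1, `"fdr"`).
#' @param pseudocount added to normalized means in the fold change
#'   (default 0.5).
#' @return A `de_result` data.frame: `gene_id`, `mean_control`,
#'   `mean_injured`, `log2fc`, `fold_change`, `p_value`, `fdr`,
#'   `significant`.
#' @export
differential_expression <- function(counts, condition, fc_threshold = 1.5,
                                    alpha = 0.1,
                                    criterion = c("fdr", "pvalue"),
                                    pseudocount = 0.5) {
  criterion <- match.arg(criterion)
  counts <- as.matrix(counts)
  if (length(unique(condition)) < 2) stop("degenerate design: one condition")
  if (!all(condition %in% c("injured", "control")))
    stop("condition must be 'injured' or 'control'")
  sf <- median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  inj <- which(condition == "injured")
  ctl <- which(condition == "control")
  m_inj <- rowMeans(norm[, inj, drop = FALSE])
  m_ctl <- rowMeans(norm[, ctl, drop = FALSE])
  fc <- (m_inj + pseudocount) / (m_ctl + pseudocount)
  phi <- mom_common_dispersion(counts, condition, sf)
  p <- nb_exact_test(counts, condition, sf, phi)
  fdr <- stats::p.adjust(p, method = "BH")
  metric <- if (criterion == "fdr") fdr else p
  out <- data.frame(gene_id = if (!is.null(rownames(counts)))
                      rownames(counts) else as.character(seq_len(nrow(counts))),
                    mean_control = m_ctl, mean_injured = m_inj,
                    log2fc = log2(fc), fold_change = fc,
                    p_value = p, fdr = fdr,
                    significant = fc >= fc_threshold & metric < alpha &
                      m_inj > m_ctl,
                    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d genes, %d significant (dispersion %.3g)\n",
              nrow(x), sum(x$significant), attr(x, "dispersion")))
  invisible(x)
}

#' Cell types recognised by the assignment procedure
#' @export
CELL_TYPES <- c("cardiomyocyte", "endothelial cell", "fibroblast",
                "epicardial cell", "perivascular cell", "smooth muscle cell",
                "macrophage", "monocyte", "T cell", "B cell")

#' Assign induced genes to cell types from scRNA data
#'
#' Per cell, counts are scaled to 10,000 and log1p-normalized:
#' `value = log1p(1e4 * count / cell_total)`. For each gene in `gene_set`
#' (typically the significantly up-regulated IRE-associated genes) and each
#' cell type, the fold change of the mean normalized value between injured
#' and uninjured cells is computed (pseudocount-guarded), and the gene is
#' assigned to the cell type with the largest fold change. Exact ties are
#' broken by the fixed order of `types`. Cell types present in only one
#' condition are excluded with a warning.
#'
#' @param sc_counts genes x cells matrix (dense or sparse; rownames = gene
#'   ids, colnames = cell ids).
#' @param cell_meta data.frame with `cell_id`, `type`, `condition`
#'   (`"injured"` / `"control"`), rows matching the columns of `sc_counts`.
#' @param gene_set character vector of genes to assign.
#' @param types cell-type universe and tie-break order (default
#'   [CELL_TYPES], restricted to the types observed).
#' @param pseudocount added to both condition means before the ratio
#'   (default 0.01).
#' @param use_abs_fc assign by largest `|log fold change|` instead of
#'   largest positive fold change when `TRUE`.
#' @return A `cell_type_assignment` list: `assignment` data.frame
#'   (`gene_id`, `cell_type`) and `fold_change` matrix (genes x types).
#' @export
assign_cell_types <- function(sc_counts, cell_meta, gene_set,
                              types = CELL_TYPES, pseudocount = 0.01,
                              use_abs_fc = FALSE) {
  stopifnot(all(c("cell_id", "type", "condition") %in% names(cell_meta)),
            nrow(cell_meta) == ncol(sc_counts))
  types <- types[types %in% cell_meta$type]
  gene_set <- gene_set[gene_set %in% rownames(sc_counts)]
  totals <- Matrix::colSums(sc_counts)
  # per-cell normalization: log1p(1e4 * count / total)
  sub <- as.matrix(sc_counts[gene_set, , drop = FALSE])
  norm <- log1p(sweep(sub, 2, totals / 1e4, "/"))
  keep <- character(0)
  for (ty in types) {
    has_inj <- any(cell_meta$type == ty & cell_meta$condition == "injured")
    has_ctl <- any(cell_meta$type == ty & cell_meta$condition == "control")
    if (has_inj && has_ctl) keep <- c(keep, ty)
    else warning("cell type present in only one condition, excluded: ", ty)
  }
  fcm <- matrix(NA_real_, nrow = length(gene_set), ncol = length(keep),
                dimnames = list(gene_set, keep))
  for (ty in keep) {
    inj <- cell_meta$type == ty & cell_meta$condition == "injured"
    ctl <- cell_meta$type == ty & cell_meta$condition == "control"
    m_inj <- rowMeans(norm[, inj, drop = FALSE])
    m_ctl <- rowMeans(norm[, ctl, drop = FALSE])
    fcm[, ty] <- (m_inj + pseudocount) / (m_ctl + pseudocount)
  }
  score <- if (use_abs_fc) abs(log(fcm)) else fcm
  assigned <- keep[apply(score, 1, which.max)]
  structure(list(assignment = data.frame(gene_id = gene_set,
                                         cell_type = assigned,
                                         stringsAsFactors = FALSE),
                 fold_change = fcm),
            class = "cell_type_assignment")
}

#' @export
print.cell_type_assignment <- function(x, ...) {
  tab <- table(x$assignment$cell_type)
  cat(sprintf("<cell_type_assignment> %d genes: %s\n",
              nrow(x$assignment),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}
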