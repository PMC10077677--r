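# Affine-gap pairwise alignment wrappers around the compiled Gotoh DP.

#' Global pairwise alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch alignment under the gap cost contract
#' `cost(L) = gap_open + L * gap_extend`, with end gaps penalized.
#' Substitution scores default to +5 (match) / -4 (mismatch); `N` scores as
#' a mismatch against everything. Traceback ties are resolved
#' diagonal > up > left, so results are deterministic.
#'
#' Aligning `"A"` against the empty string therefore scores
#' `-(10 + 1 * 0.5) = -10.5` under the defaults — this pins the gap-cost
#' convention.
#'
#' @param a,b nucleotide strings over A,C,G,T,N (case-insensitive).
#' @param gap_open gap opening penalty (default 10).
#' @param gap_extend per-base gap extension penalty (default 0.5).
#' @param match,mismatch substitution scores (defaults +5 / -4).
#' @return An `alignment_result`: list with `score`, `pct_identity`
#'   (matches / alignment columns x 100), `aligned_a`, `aligned_b`,
#'   `query_span` and `target_span` (0-based half-open offsets of the
#'   aligned, both-non-gap core in `a` and `b`; `NULL` when no column aligns
#'   both sequences).
#' @examples
#' global_align("ACGT", "ACGT")$score   # 20
#' global_align("ACGT", "ACCT")$score   # 11
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         match = 5, mismatch = -4) {
  a <- toupper(a); b <- toupper(b)
  res <- .nw_global(a, b, match, mismatch, gap_open, gap_extend)
  build_alignment_result(res$score, res$aligned_a, res$aligned_b,
                         a_offset = 0L, b_offset = 0L)
}

build_alignment_result <- function(score, aligned_a, aligned_b,
                                   a_offset = 0L, b_offset = 0L) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  ncol_aln <- length(ca)
  both <- which(ca != "-" & cb != "-")
  matches <- sum(ca == cb & ca != "-" & ca != "N")
  identity <- if (ncol_aln > 0) 100 * matches / ncol_aln else NA_real_
  span <- function(chars, cols, offset) {
    if (length(cols) == 0) return(NULL)
    pos <- cumsum(chars != "-")  # residue index at each column
    c(start = offset + pos[cols[1]] - 1L, end = offset + pos[cols[length(cols)]])
  }
  structure(list(score = score,
                 pct_identity = identity,
                 n_matches = matches,
                 n_columns = ncol_aln,
                 aligned_a = aligned_a,
                 aligned_b = aligned_b,
                 query_span = span(ca, both, a_offset),
                 target_span = span(cb, both, b_offset)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score = %.1f, identity = %.1f%% over %d columns\n",
              x$score, x$pct_identity, x$n_columns))
  if (x$n_columns > 0 && x$n_columns <= 80) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  }
  invisible(x)
}

#' Glocal alignment of a query against a long target window
#'
#' Aligns the full query end-to-end while leaving the leading and trailing
#' flanks of the target window unaligned at no cost ("glocal" mode). This is
#' the alignment used for orthologous-enhancer mapping, where a ~1 kb
#' enhancer is searched within a 200 kb window: the DP locates the aligned
#' core with linear memory, then an exact traceback pass over the core
#' produces the alignment strings. Identity is computed over the core
#' alignment columns (flanks excluded).
#'
#' For query-window products above `max_exact_cells` the quadratic DP is
#' first localized by seed matching: exact query k-mers are looked up in the
#' window, hits vote for their diagonal, and the exact glocal DP is run on
#' the subwindow around the winning diagonal (with a generous margin). When
#' no clear anchor emerges the full exact DP is used regardless.
#'
#' @inheritParams global_align
#' @param max_exact_cells cell-count threshold above which seed
#'   localization precedes the exact DP (default 4e7).
#' @param seed_k k-mer size for seed localization (default 12).
#' @return An `alignment_result` whose `target_span` holds the 0-based
#'   half-open span of the aligned core within `b`.
#' @export
glocal_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         match = 5, mismatch = -4,
                         max_exact_cells = 4e7, seed_k = 12) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0) {
    return(build_alignment_result(0, "", ""))
  }
  cells <- as.double(nchar(a)) * as.double(nchar(b))
  if (cells > max_exact_cells && nchar(a) > seed_k) {
    anchor <- seed_anchor_window(a, b, k = seed_k)
    if (!is.null(anchor)) {
      sub_b <- substr(b, anchor[1] + 1L, anchor[2])
      out <- glocal_align_exact(a, sub_b, gap_open, gap_extend, match,
                                mismatch, b_offset = anchor[1])
      return(out)
    }
  }
  glocal_align_exact(a, b, gap_open, gap_extend, match, mismatch,
                     b_offset = 0L)
}

glocal_align_exact <- function(a, b, gap_open, gap_extend, match, mismatch,
                               b_offset = 0L) {
  loc <- .glocal_locate(a, b, match, mismatch, gap_open, gap_extend)
  core_b <- substr(b, loc$j_start + 1L, loc$j_end)
  sub <- .nw_global(a, core_b, match, mismatch, gap_open, gap_extend)
  out <- build_alignment_result(sub$score, sub$aligned_a, sub$aligned_b,
                                a_offset = 0L,
                                b_offset = b_offset + as.integer(loc$j_start))
  # the core global alignment realizes the glocal optimum
  stopifnot(abs(out$score - loc$score) < 1e-6)
  out
}

# Locate the query's home in a long window by exact k-mer diagonal voting.
# Returns c(start0, end0) of the candidate subwindow (0-based half-open),
# or NULL when no diagonal collects enough votes to be trusted.
seed_anchor_window <- function(a, b, k = 12, min_votes = 5, diag_bin = 100) {
  la <- nchar(a); lb <- nchar(b)
  qpos <- seq_len(la - k + 1L)
  wpos <- seq_len(lb - k + 1L)
  qk <- substring(a, qpos, qpos + k - 1L)
  wk <- substring(b, wpos, wpos + k - 1L)
  m <- match(wk, qk)
  hit_w <- which(!is.na(m))
  if (length(hit_w) == 0) return(NULL)
  hit_q <- m[hit_w]
  diag <- hit_w - hit_q
  bins <- round(diag / diag_bin)
  tab <- table(bins)
  best_bin <- as.integer(names(tab)[which.max(tab)])
  votes <- max(tab)
  if (votes < min_votes) return(NULL)
  sel <- abs(bins - best_bin) <= 1
  lo <- min(hit_w[sel]) - 1L   # 0-based
  hi <- max(hit_w[sel]) + k - 1L
  margin <- la + 2L * diag_bin
  c(max(0L, lo - margin), min(lb, hi + margin))
}
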