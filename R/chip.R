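# Region-level signal quantification and differential enhancer (IRE)
# calling.
#
# The differential test is a two-group negative-binomial exact-style test
# with a single method-of-moments dispersion shared across regions:
# per-group sums of library-size-adjusted counts are compared through the
# conditional distribution of one group's sum given the total, with
# p-values summed over outcomes no more probable than the observed one.
# Benjamini-Hochberg controls the FDR across regions.

#' Build a region count table
#'
#' @param regions interval data.frame (one row per region).
#' @param counts integer matrix, regions x samples.
#' @param condition per-sample condition, `"injured"` or `"control"`.
#' @param replicate optional per-sample replicate ids.
#' @param lib_size per-sample library sizes; defaults to the column sums
#'   (must be at least the column sums when supplied).
#' @return A `region_count_table` list.
#' @export
region_count_table <- function(regions, counts, condition, replicate = NULL,
                               lib_size = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(regions),
            ncol(counts) == length(condition))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(condition %in% c("injured", "control")))
    stop("condition must be 'injured' or 'control'")
  if (is.null(replicate)) replicate <- stats::ave(seq_along(condition),
                                                  condition, FUN = seq_along)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size < colSums(counts)))
    stop("library size below column sum")
  if (any(lib_size <= 0)) stop("empty library")
  structure(list(regions = regions, counts = counts,
                 sample_meta = data.frame(condition = condition,
                                          replicate = replicate,
                                          lib_size = lib_size,
                                          stringsAsFactors = FALSE)),
            class = "region_count_table")
}

#' @export
print.region_count_table <- function(x, ...) {
  cat(sprintf("<region_count_table> %d regions x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$sample_meta$condition, collapse = ", ")))
  invisible(x)
}

#' Count signal over regions
#'
#' Sums per-base coverage of a signal track within each region. The track is
#' a bedGraph-style data.frame (`chrom`, `start`, `end`, `value`; 0-based
#' half-open). Overlapping track intervals are summed. Regions extending
#' beyond the track are clipped (coverage 0 outside), with a warning when
#' chromosome lengths are supplied and exceeded.
#'
#' @param track bedGraph-style data.frame.
#' @param regions interval data.frame.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return Numeric vector of per-region coverage sums.
#' @export
region_counts <- function(track, regions, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    over <- regions$end > chrom_lengths[regions$chrom]
    if (any(over, na.rm = TRUE)) warning("region(s) beyond chromosome bound; clipped")
  }
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next
    q <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    s <- IRanges::IRanges(tr$start + 1L, tr$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                            s[S4Vectors::subjectHits(ov)]))
    contrib <- w * tr$value[S4Vectors::subjectHits(ov)]
    sums <- tapply(contrib, S4Vectors::queryHits(ov), sum)
    out[ri[as.integer(names(sums))]] <- as.numeric(sums)
  }
  out
}

# Method-of-moments common NB dispersion across regions and conditions.
# For normalized counts z = y / s: E z = mu, Var z_j = mu / s_j + phi mu^2;
# within each (region, condition) group the sample variance of z is matched
# to that form and the estimates pooled, weighted by mu^2.
mom_common_dispersion <- function(counts, condition, size_factors) {
  num <- 0; den <- 0
  for (cond in unique(condition)) {
    j <- which(condition == cond)
    if (length(j) < 2) next
    s <- size_factors[j]
    z <- sweep(counts[, j, drop = FALSE], 2, s, "/")
    m <- rowMeans(z)
    v <- apply(z, 1, stats::var)
    a <- mean(1 / s)
    num <- num + sum(v - m * a)
    den <- den + sum(m^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# Exact-style conditional two-group NB test. Counts are adjusted to a
# common library size, summed per group, and the probability of each split
# of the total between the two group sums (each NB with size n_g / phi) is
# enumerated; p is the total probability of splits no more probable than
# the observed one. phi = 0 falls back to the Poisson (binomial
# conditional) limit.
nb_exact_test <- function(counts, condition, size_factors, phi,
                          max_enum = 50000) {
  g1 <- which(condition == unique(condition)[1])
  g2 <- which(condition != unique(condition)[1])
  n1 <- length(g1); n2 <- length(g2)
  adj <- sweep(counts, 2, size_factors, "/")
  A <- round(rowSums(adj[, g1, drop = FALSE]))
  B <- round(rowSums(adj[, g2, drop = FALSE]))
  total <- A + B
  p <- rep(1, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    tot <- total[i]
    if (tot == 0) next
    if (tot > max_enum) {
      # normal approximation to the conditional distribution for very deep
      # regions
      mu <- tot * n1 / (n1 + n2)
      mu_per <- tot / (n1 + n2)
      v <- n1 * (mu_per + phi * mu_per^2) * n2 / (n1 + n2)
      z <- (A[i] - mu) / sqrt(v)
      p[i] <- 2 * stats::pnorm(-abs(z))
      next
    }
    k <- 0:tot
    if (phi > 0) {
      lp <- stats::dnbinom(k, size = n1 / phi, mu = n1 * tot / (n1 + n2),
                           log = TRUE) +
        stats::dnbinom(tot - k, size = n2 / phi, mu = n2 * tot / (n1 + n2),
                       log = TRUE)
    } else {
      lp <- stats::dbinom(k, tot, n1 / (n1 + n2), log = TRUE)
    }
    lp <- lp - max(lp)
    pr <- exp(lp); pr <- pr / sum(pr)
    obs <- pr[A[i] + 1]
    p[i] <- min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }
  p
}

#' Call differential (injury-responsive) regions
#'
#' Computes, per region, library-size-normalized condition means, the
#' pseudocounted fold change
#' `(mean_injured + pc) / (mean_control + pc)`, a two-group
#' negative-binomial exact-style p-value with a common method-of-moments
#' dispersion, and BH-adjusted FDR. A region is called `IRE` when its fold
#' change reaches `fc_threshold` and the chosen criterion metric (FDR or raw
#' p-value) is below `alpha` — the mouse-style rule is FC > 1.5 at
#' FDR < 0.05, the zebrafish-style rule FC > 1.5 at p < 0.01. Regions not
#' called but active in both conditions (mean normalized counts of at least
#' `activity_floor` counts per million in each) are `non-IRE`; the remainder
#' are `excluded`.
#'
#' With a single replicate in every condition no dispersion can be
#' estimated and the test falls back to the Poisson limit, with a warning.
#'
#' @param table a [region_count_table()].
#' @param fc_threshold fold-change threshold (ratio scale, default 1.5).
#' @param alpha significance level (default 0.05).
#' @param criterion `"fdr"` or `"pvalue"`.
#' @param pseudocount added to normalized means in the fold change
#'   (default 0.5).
#' @param activity_floor minimum mean normalized count per million per
#'   condition for a region to count as active (default 1).
#' @return A `differential_result` data.frame: region columns plus
#'   `mean_control`, `mean_injured`, `log2fc`, `fold_change`, `p_value`,
#'   `fdr`, `call`. The estimated dispersion is attached as attribute
#'   `dispersion`.
#' @export
call_differential_regions <- function(table, fc_threshold = 1.5,
                                      alpha = 0.05,
                                      criterion = c("fdr", "pvalue"),
                                      pseudocount = 0.5,
                                      activity_floor = 1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(table, "region_count_table"))
  counts <- table$counts
  meta <- table$sample_meta
  if (any(colSums(counts) == 0) && any(meta$lib_size == 0))
    stop("empty library")
  sf <- meta$lib_size / mean(meta$lib_size)
  inj <- which(meta$condition == "injured")
  ctl <- which(meta$condition == "control")
  if (length(inj) == 0 || length(ctl) == 0)
    stop("both conditions must be present")
  norm <- sweep(counts, 2, sf, "/")
  m_inj <- rowMeans(norm[, inj, drop = FALSE])
  m_ctl <- rowMeans(norm[, ctl, drop = FALSE])
  fc <- (m_inj + pseudocount) / (m_ctl + pseudocount)
  log2fc <- log2(fc)
  has_reps <- length(inj) >= 2 || length(ctl) >= 2
  if (has_reps) {
    phi <- mom_common_dispersion(counts, meta$condition, sf)
  } else {
    warning("no replicates; falling back to Poisson dispersion")
    phi <- 0
  }
  cond12 <- ifelse(meta$condition == "injured", "injured", "control")
  # order groups so that group 1 = injured for the conditional test
  ord_cond <- factor(cond12, levels = c("injured", "control"))
  p <- nb_exact_test(counts, as.character(ord_cond), sf, phi)
  fdr <- stats::p.adjust(p, method = "BH")
  metric <- if (criterion == "fdr") fdr else p
  cpm_inj <- rowMeans(sweep(counts[, inj, drop = FALSE], 2,
                            meta$lib_size[inj], "/")) * 1e6
  cpm_ctl <- rowMeans(sweep(counts[, ctl, drop = FALSE], 2,
                            meta$lib_size[ctl], "/")) * 1e6
  is_ire <- fc >= fc_threshold & metric < alpha & m_inj > m_ctl
  active_both <- cpm_inj >= activity_floor & cpm_ctl >= activity_floor
  call <- ifelse(is_ire, "IRE", ifelse(active_both, "non-IRE", "excluded"))
  out <- cbind(as.data.frame(table$regions),
               data.frame(mean_control = m_ctl, mean_injured = m_inj,
                          log2fc = log2fc, fold_change = fc,
                          p_value = p, fdr = fdr, call = call,
                          stringsAsFactors = FALSE))
  attr(out, "dispersion") <- phi
  attr(out, "criterion") <- criterion
  class(out) <- c("differential_result", "data.frame")
  out
}

#' @export
print.differential_result <- function(x, ...) {
  tab <- table(x$call)
  cat(sprintf("<differential_result> %d regions (dispersion %.3g): %s\n",
              nrow(x), attr(x, "dispersion"),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Define IREs and non-IREs from differential calls
#'
#' Applies the distal-enhancer rule on top of the differential calls: IREs
#' are the up-called peaks at least `flank` bp (midpoint rule) from any
#' TSS; up-called but promoter-proximal peaks are excluded; remaining
#' active peaks are non-IREs. The three classes partition the peaks.
#'
#' @param diff a `differential_result` from [call_differential_regions()]
#'   computed on the same peaks.
#' @param genes gene model data.frame.
#' @param flank promoter half-width (default 2000).
#' @return The `diff` data.frame with an additional `class` column in
#'   `{IRE, non-IRE, excluded}`.
#' @export
define_ires <- function(diff, genes, flank = 2000) {
  prox <- promoter_proximal(diff, genes, flank)
  cls <- diff$call
  cls[cls == "IRE" & prox] <- "excluded"
  out <- diff
  out$class <- cls
  out
}

#' Signal matrix around anchors
#'
#' Bins coverage of a signal track in windows of +/- `flank` around anchor
#' points — region centers, or TSSs when `anchors` is a gene model table
#' (minus-strand windows are flipped so bins read 5' to 3'). Cell (i, j) is
#' the mean per-base coverage in bin j of anchor i; bases beyond the
#' chromosome are counted as zero coverage (with a warning). The column
#' means form the metagene profile.
#'
#' @param track bedGraph-style data.frame.
#' @param anchors interval data.frame (anchored at midpoints) or
#'   `gene_models` data.frame (anchored at TSSs).
#' @param flank half-window in bp (default 5000); must be divisible by
#'   `bin`.
#' @param bin bin width in bp.
#' @param chrom_lengths optional named chromosome lengths (defaults to the
#'   track extent).
#' @return A `signal_matrix`: list with `values` (anchors x bins), `flank`,
#'   `bin_width`, `profile` (column means).
#' @export
signal_matrix <- function(track, anchors, flank = 5000, bin = 100,
                          chrom_lengths = NULL) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  nb <- as.integer(2 * flank / bin)
  if (inherits(anchors, "gene_models")) {
    centers <- anchors$tss
    strands <- anchors$strand
  } else {
    centers <- interval_midpoint(anchors)
    strands <- rep("+", nrow(anchors))
  }
  chroms <- anchors$chrom
  n <- length(centers)
  vals <- matrix(0, nrow = n, ncol = nb)
  warned <- FALSE
  for (ch in unique(chroms)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else if (nrow(tr) > 0) max(tr$end) else 0L
    cov <- if (nrow(tr) > 0) {
      IRanges::coverage(IRanges::IRanges(tr$start + 1L, tr$end),
                        weight = tr$value, width = max(len, max(tr$end)))
    } else S4Vectors::Rle(0, max(len, 1L))
    covlen <- length(cov)
    for (i in which(chroms == ch)) {
      starts0 <- centers[i] - flank + bin * (seq_len(nb) - 1L)  # 0-based
      ends0 <- starts0 + bin
      if ((starts0[1] < 0 || ends0[nb] > covlen) && !warned &&
          (starts0[1] < 0 || (!is.null(chrom_lengths) && ends0[nb] > len))) {
        warning("anchor window extends beyond chromosome; zero-padded")
        warned <- TRUE
      }
      cs <- pmax(starts0, 0L); ce <- pmin(ends0, covlen)
      ok <- cs < ce
      sums <- numeric(nb)
      if (any(ok)) {
        v <- IRanges::Views(cov, start = cs[ok] + 1L, end = ce[ok])
        sums[ok] <- IRanges::viewSums(v)
      }
      row <- sums / bin
      if (strands[i] == "-") row <- rev(row)
      vals[i, ] <- row
    }
  }
  structure(list(values = vals, flank = flank, bin_width = bin,
                 profile = colMeans(vals)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d anchors x %d bins (flank %d, bin %d)\n",
              nrow(x$values), ncol(x$values), x$flank, x$bin_width))
  invisible(x)
}

#' Classify enhancer chromatin states by k-means
#'
#' Clusters enhancers (k = 3) on the concatenated H3K27ac and H3K27me3
#' signal-matrix rows, then names the clusters by their mean signals:
#' highest mean H3K27me3 is `poised`; of the remaining two, the higher mean
#' H3K27ac is `active` and the other `primed`. k-means uses 10 random
#' restarts under a fixed seed.
#'
#' @param ac_matrix,me3_matrix row-aligned [signal_matrix()] objects (same
#'   enhancers).
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return Character vector of labels (`poised`, `primed`, `active`), one
#'   per enhancer.
#' @export
classify_enhancer_states <- function(ac_matrix, me3_matrix, k = 3, seed = 1,
                                     nstart = 10) {
  ac <- ac_matrix$values
  me3 <- me3_matrix$values
  stopifnot(nrow(ac) == nrow(me3))
  if (k > nrow(ac)) stop("k exceeds the number of enhancers")
  x <- cbind(ac, me3)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  mean_ac <- tapply(rowMeans(ac), km$cluster, mean)
  mean_me3 <- tapply(rowMeans(me3), km$cluster, mean)
  labels <- rep(NA_character_, k)
  poised <- as.integer(names(which.max(mean_me3)))
  labels[poised] <- "poised"
  rest <- setdiff(seq_len(k), poised)
  active <- rest[which.max(mean_ac[as.character(rest)])]
  labels[active] <- "active"
  labels[setdiff(rest, active)] <- "primed"
  labels[km$cluster]
}

#' Mean conservation score in a window around region midpoints
#'
#' Averages per-base scores (e.g. phastCons or phyloP) over the window
#' `[midpoint - window/2, midpoint + window/2)`. Bases not covered by the
#' score track are treated as missing and excluded from the mean; a fully
#' missing window yields `NA` rather than zero.
#'
#' @param score_track bedGraph-style data.frame of per-base scores.
#' @param regions interval data.frame.
#' @param window window width in bp (default 1000; must be even).
#' @return Numeric vector of per-region mean scores (`NA` when undefined).
#' @export
conservation_window_mean <- function(score_track, regions, window = 1000) {
  if (window %% 2 != 0) stop("window must be even")
  mid <- interval_midpoint(regions)
  half <- window %/% 2
  out <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    tr <- score_track[score_track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next
    q <- IRanges::IRanges(pmax(mid[ri] - half, 0L) + 1L, mid[ri] + half)
    s <- IRanges::IRanges(tr$start + 1L, tr$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                            s[S4Vectors::subjectHits(ov)]))
    val <- tr$value[S4Vectors::subjectHits(ov)]
    qh <- S4Vectors::queryHits(ov)
    sums <- tapply(w * val, qh, sum)
    wts <- tapply(w, qh, sum)
    idx <- as.integer(names(sums))
    out[ri[idx]] <- as.numeric(sums) / as.numeric(wts)
  }
  out
}
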