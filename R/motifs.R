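# IUPAC degenerate motif scanning and the per-kilobase frequency statistic.
#
# The scanner tests every sliding-window offset (overlapping matches are
# counted) against a degenerate code; an N in the subject sequence matches
# only an N in the pattern. Soft-masked (lowercase) bases are uppercased
# before scanning.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Construct an IUPAC motif pattern
#'
#' @param name transcription factor or family name.
#' @param iupac degenerate code over A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N; length
#'   at least 4.
#' @param family one of `"AP-1"`, `"ETS"`, `"other"`.
#' @return A `motif_pattern` object.
#' @examples
#' motif_pattern("AP-1", "TKASTMA", family = "AP-1")
#' @export
motif_pattern <- function(name, iupac, family = c("other", "AP-1", "ETS")) {
  family <- match.arg(family)
  iupac <- toupper(iupac)
  letters <- strsplit(iupac, "")[[1]]
  if (length(letters) < 4) stop("IUPAC pattern must have length >= 4")
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ","))
  structure(list(name = name, family = family, iupac = iupac),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s [%s] %s\n", x$name, x$family, x$iupac))
  invisible(x)
}

#' Reverse complement of an IUPAC code
#'
#' @param iupac degenerate code string.
#' @return The reverse-complement code. The AP-1 consensus `TKASTMA` is its
#'   own reverse complement (a degenerate palindrome); the ETS consensus
#'   `VVGGAWVY` is not.
#' @export
iupac_reverse_complement <- function(iupac) {
  letters <- rev(strsplit(toupper(iupac), "")[[1]])
  paste(IUPAC_COMPLEMENT[letters], collapse = "")
}

# 0-based offsets at which `pattern_letters` matches `seq_letters`
iupac_match_offsets <- function(seq_letters, pattern_letters) {
  n <- length(seq_letters)
  k <- length(pattern_letters)
  if (n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (p in seq_len(k)) {
    allowed <- IUPAC_SETS[[pattern_letters[p]]]
    ok <- ok & (seq_letters[p:(n - k + p)] %in% allowed)
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

#' Scan a sequence for a degenerate motif
#'
#' All (possibly overlapping) sliding-window matches are reported. Strand
#' handling:
#' \describe{
#'   \item{`forward`}{matches of the pattern on the given strand only.}
#'   \item{`both_dedup`}{unique forward-coordinate windows matched on either
#'     strand (a window hit on both strands is counted once). The default.}
#'   \item{`both_sum`}{strand matches counted independently and summed.}
#' }
#'
#' @param sequence nucleotide string over A,C,G,T,N (case-insensitive).
#' @param pattern a [motif_pattern()].
#' @param strand_mode `"forward"`, `"both_dedup"` or `"both_sum"`.
#' @return A `motif_hits` object: list with `pattern`, `s` (sequence length),
#'   `c` (match count), `f` (per-kb frequency, `1000 * c / s`), and
#'   `positions` (data.frame of 0-based `offset` and `strand`).
#' @examples
#' ap1 <- motif_pattern("AP-1", "TKASTMA", "AP-1")
#' scan_motif("TGACTCATGACTCA", ap1)$c
#' @export
scan_motif <- function(sequence, pattern,
                       strand_mode = c("both_dedup", "forward", "both_sum")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(pattern, "motif_pattern"))
  seq_letters <- strsplit(toupper(sequence), "")[[1]]
  pat <- strsplit(pattern$iupac, "")[[1]]
  fwd <- iupac_match_offsets(seq_letters, pat)
  if (strand_mode == "forward") {
    pos <- data.frame(offset = fwd,
                      strand = rep("+", length(fwd)),
                      stringsAsFactors = FALSE)
  } else {
    rcpat <- strsplit(iupac_reverse_complement(pattern$iupac), "")[[1]]
    rev_hits <- iupac_match_offsets(seq_letters, rcpat)
    if (strand_mode == "both_dedup") {
      offs <- sort(union(fwd, rev_hits))
      pos <- data.frame(offset = offs,
                        strand = ifelse(offs %in% fwd, "+", "-"),
                        stringsAsFactors = FALSE)
    } else {
      pos <- data.frame(offset = c(fwd, rev_hits),
                        strand = rep(c("+", "-"),
                                     c(length(fwd), length(rev_hits))),
                        stringsAsFactors = FALSE)
      pos <- pos[order(pos$offset, pos$strand), , drop = FALSE]
      rownames(pos) <- NULL
    }
  }
  s <- length(seq_letters)
  cnt <- nrow(pos)
  structure(list(pattern = pattern, s = s, c = cnt,
                 f = if (s > 0) motif_frequency(cnt, s) else 0,
                 positions = pos),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("<motif_hits> %s (%s): c = %d over s = %d bp, f = %.3f /kb\n",
              x$pattern$name, x$pattern$iupac, x$c, x$s, x$f))
  invisible(x)
}

#' Motif frequency per kilobase
#'
#' `f = 1000 * c / s`, where `c` is the motif count and `s` the sequence
#' size in bp. For example, an 800 bp enhancer containing 6 ETS motifs has
#' an ETS frequency of 7.5 per kb.
#'
#' @param c non-negative motif count(s).
#' @param s sequence size(s) in bp, `> 0`.
#' @return Frequency per kilobase.
#' @export
motif_frequency <- function(c, s) {
  if (any(s <= 0)) stop("sequence size s must be > 0")
  if (any(c < 0)) stop("motif count c must be >= 0")
  1000 * c / s
}

#' Built-in AP-1 and ETS motif registry
#'
#' The two family consensus codes (AP-1 `TKASTMA`, ETS `VVGGAWVY`) plus the
#' 21 per-factor degenerate codes (14 ETS factors, 7 AP-1 factors) used for
#' per-factor frequency comparisons.
#'
#' @param family optional filter: `"AP-1"` or `"ETS"`.
#' @param consensus_only if `TRUE`, only the two family consensus codes.
#' @return data.frame with columns `name`, `family`, `iupac`, `consensus`.
#' @export
motif_registry <- function(family = NULL, consensus_only = FALSE) {
  reg <- data.frame(
    name = c("AP-1", "ETS",
             "EHF", "ELF1", "ELF3", "ELF4", "ELF5", "ERG", "ETS1", "ETV1",
             "ETV2", "ETV4", "FLI1", "GABPA", "PU.1", "SPIB",
             "ATF3", "BATF", "FOS", "FRA1", "FRA2", "JUN", "JUNB"),
    family = c("AP-1", "ETS", rep("ETS", 14), rep("AP-1", 7)),
    iupac = c("TKASTMA", "VVGGAWVY",
              "DNVMGGAAR", "SCGGAAGY", "WNVMGGAARY", "VMGGAAG", "WNVMGGAAGT",
              "CMGGAARY", "RVMGGAWRY", "CMGGAWG", "VMGGAWR", "SMGGAWRB",
              "VMGGAWR", "VMGGAAG", "DVRGGAAGTG", "DWDVRGAAVYS",
              "VTKANTCAB", "TKASTMA", "TKANTYA", "VTKANTMAB", "TKWSYMA",
              "TGASTCA", "TKASTCA"),
    consensus = c(TRUE, TRUE, rep(FALSE, 21)),
    stringsAsFactors = FALSE)
  if (consensus_only) reg <- reg[reg$consensus, , drop = FALSE]
  if (!is.null(family)) reg <- reg[reg$family == family, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Look up a registry motif as a pattern object
#' @param name registry name (e.g. `"AP-1"`, `"ETS"`, `"JUN"`).
#' @return A [motif_pattern()].
#' @export
registry_pattern <- function(name) {
  reg <- motif_registry()
  row <- reg[reg$name == name, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown registry motif: ", name)
  motif_pattern(row$name, row$iupac, row$family)
}

#' Classify regions by AP-1/ETS motif presence
#'
#' Labels each region (typically an IRE) by the presence (count >= 1) of the
#' AP-1 and ETS family motifs: `"AP-1 only"`, `"ETS only"`, `"both"`, or
#' `"neither"`. The four group counts always sum to the number of regions.
#'
#' @param regions interval data.frame.
#' @param genome named genome (see [region_sequences()]).
#' @param ap1,ets [motif_pattern()] objects; default the family consensus
#'   codes.
#' @param strand_mode passed to [scan_motif()].
#' @return List with `labels` (character per region) and `counts` (named
#'   integer vector over the four groups).
#' @export
classify_motif_groups <- function(regions, genome,
                                  ap1 = registry_pattern("AP-1"),
                                  ets = registry_pattern("ETS"),
                                  strand_mode = "both_dedup") {
  seqs <- region_sequences(regions, genome)
  has_ap1 <- vapply(seqs, function(s)
    scan_motif(s, ap1, strand_mode)$c >= 1, logical(1), USE.NAMES = FALSE)
  has_ets <- vapply(seqs, function(s)
    scan_motif(s, ets, strand_mode)$c >= 1, logical(1), USE.NAMES = FALSE)
  labels <- ifelse(has_ap1 & has_ets, "both",
            ifelse(has_ap1, "AP-1 only",
            ifelse(has_ets, "ETS only", "neither")))
  lev <- c("AP-1 only", "ETS only", "both", "neither")
  counts <- table(factor(labels, levels = lev))
  list(labels = labels, counts = stats::setNames(as.integer(counts), lev))
}

#' GC fraction of sequences or regions
#' @param x character vector of sequences.
#' @return Fraction of G/C among non-N bases.
#' @export
gc_content <- function(x) {
  vapply(toupper(x), function(s) {
    l <- strsplit(s, "")[[1]]
    acgt <- l %in% c("A", "C", "G", "T")
    if (!any(acgt)) return(NA_real_)
    mean(l[acgt] %in% c("C", "G"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sample a GC-matched background region set
#'
#' Selects `n` regions from a candidate pool so that their per-region GC
#' fractions reproduce the GC histogram of the target regions, using bins of
#' width `gc_tolerance` (every selected region sits within one bin, i.e.
#' within +/- `gc_tolerance`, of some target region's GC). Sampling is
#' without replacement and reproducible under `seed`. With
#' `match_gc = FALSE` the pool is sampled uniformly instead (used e.g. for
#' random promoter selection).
#'
#' @param pool candidate regions (interval data.frame).
#' @param targets target regions whose GC distribution is matched.
#' @param genome named genome the pool is drawn from.
#' @param n number of background regions to draw.
#' @param gc_tolerance GC bin width (default 0.02).
#' @param seed integer RNG seed.
#' @param match_gc disable GC matching (uniform sampling) when `FALSE`.
#' @param target_genome genome for the target regions (defaults to
#'   `genome`).
#' @return Subset of `pool` with `n` rows.
#' @export
gc_matched_background <- function(pool, targets, genome, n,
                                  gc_tolerance = 0.02, seed = 1,
                                  match_gc = TRUE, target_genome = genome) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  if (!match_gc) {
    if (n > nrow(pool)) stop("pool smaller than n")
    idx <- sample.int(nrow(pool), n)
    return(pool[sort(idx), , drop = FALSE])
  }
  gc_pool <- gc_content(region_sequences(pool, genome))
  gc_tgt <- gc_content(region_sequences(targets, target_genome))
  edges <- seq(0, 1 + gc_tolerance, by = gc_tolerance)
  bin_pool <- findInterval(gc_pool, edges, rightmost.closed = TRUE)
  bin_tgt <- findInterval(gc_tgt, edges, rightmost.closed = TRUE)
  # allocate n across target GC bins by largest remainder
  tab <- table(bin_tgt)
  want <- as.numeric(tab) / length(bin_tgt) * n
  base <- floor(want)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(want - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  names(base) <- names(tab)
  picked <- integer(0)
  for (b in names(base)) {
    need <- base[[b]]
    if (need == 0) next
    avail <- which(bin_pool == as.integer(b))
    if (length(avail) < need) {
      lo <- (as.integer(b) - 1) * gc_tolerance
      stop(sprintf(
        "insufficient pool in GC bin [%.2f, %.2f): need %d, have %d",
        lo, lo + gc_tolerance, need, length(avail)))
    }
    picked <- c(picked, avail[sample.int(length(avail), need)])
  }
  pool[sort(picked), , drop = FALSE]
}

#' Motif presence enrichment (Fisher exact)
#'
#' A presence/absence two-by-two test of a motif in foreground regions
#' against a (typically GC-matched) background: two-sided Fisher exact
#' p-value and odds ratio (with a Haldane 0.5 correction when a cell is
#' zero). This is a deliberately simple presence-based enrichment statistic,
#' not a log-odds motif-model enrichment.
#'
#' @param fore,back interval data.frames.
#' @param genome named genome.
#' @param pattern a [motif_pattern()].
#' @param strand_mode passed to [scan_motif()].
#' @return An `enrichment_result` list: `motif`, `fore_present`, `fore_total`,
#'   `back_present`, `back_total`, `odds_ratio`, `p_value`.
#' @export
motif_presence_enrichment <- function(fore, back, genome, pattern,
                                      strand_mode = "both_dedup") {
  if (nrow(fore) == 0 || nrow(back) == 0)
    stop("fore and back must be non-empty")
  present <- function(regions) {
    seqs <- region_sequences(regions, genome)
    sum(vapply(seqs, function(s) scan_motif(s, pattern, strand_mode)$c >= 1,
               logical(1)))
  }
  a <- present(fore); b <- nrow(fore) - a
  c_ <- present(back); d <- nrow(back) - c_
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                          alternative = "two.sided")$p.value
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5  # Haldane correction
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  structure(list(motif = pattern$name, fore_present = a, fore_total = nrow(fore),
                 back_present = c_, back_total = nrow(back),
                 odds_ratio = or, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> %s: fore %d/%d vs back %d/%d, OR = %.3g, p = %.3g\n",
    x$motif, x$fore_present, x$fore_total, x$back_present, x$back_total,
    x$odds_ratio, x$p_value))
  invisible(x)
}

#' Relative overlapping ratio by motif-frequency bin
#'
#' Bins sequences (typically random 1 kb genomic sequences) by their motif
#' frequency and, within each bin, counts how many overlap at least one TF
#' peak. The relative overlapping ratio is `r_i = n_i / n_0`, where `n_0`
#' counts the motif-free (zero-frequency) sequences that overlap peaks. A
#' shuffled-peak control (peaks repositioned uniformly at random on their own
#' chromosome, lengths preserved, seeded) is computed alongside; under no
#' association its curve stays near 1.
#'
#' @param regions interval data.frame with a numeric `frequency` column
#'   (per-kb motif frequency of each region, e.g. from [scan_motif()]).
#' @param peaks TF peak intervals.
#' @param bins right edges of the positive-frequency bins (e.g.
#'   `c(2, 4, Inf)`); frequency exactly 0 forms bin 0.
#' @param chrom_lengths named integer vector of chromosome lengths (needed
#'   for the shuffled control).
#' @param seed RNG seed for the shuffle.
#' @return An `overlap_ratio_curve`: list of two data.frames (`true`,
#'   `shuffled`) with `bin`, `n_total`, `n_overlap`, `r` per frequency bin.
#' @export
relative_overlap_ratio <- function(regions, peaks, bins, chrom_lengths,
                                   seed = 1) {
  stopifnot("frequency" %in% names(regions))
  f <- regions$frequency
  bin_idx <- ifelse(f == 0, 0L, findInterval(f, c(0, bins), left.open = TRUE))
  curve <- function(pk) {
    hit <- intersect_any(regions, pk)
    levs <- sort(unique(c(0L, bin_idx)))
    n_total <- vapply(levs, function(b) sum(bin_idx == b), integer(1))
    n_over <- vapply(levs, function(b) sum(hit & bin_idx == b), integer(1))
    n0 <- n_over[levs == 0L]
    if (length(n0) == 0 || n0 == 0) stop("empty reference bin")
    data.frame(bin = levs, n_total = n_total, n_overlap = n_over,
               r = n_over / n0)
  }
  true_curve <- curve(peaks)
  set.seed(seed)
  shuf <- peaks
  len <- shuf$end - shuf$start
  maxstart <- chrom_lengths[shuf$chrom] - len
  shuf$start <- as.integer(floor(stats::runif(nrow(shuf)) * (maxstart + 1)))
  shuf$end <- shuf$start + len
  structure(list(true = true_curve, shuffled = curve(shuf)),
            class = "overlap_ratio_curve")
}
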