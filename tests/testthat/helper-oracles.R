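# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

random_seq <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Expand an IUPAC code into its full concrete word set
expand_iupac <- function(iupac) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  letters <- strsplit(iupac, "")[[1]]
  words <- ""
  for (l in letters) {
    words <- as.vector(outer(words, sets[[l]], paste0))
  }
  words
}

# Brute-force scanner: string-search every concrete word of the code
# (overlap-aware via a lookahead), 0-based offsets
oracle_scan_offsets <- function(sequence, iupac) {
  offs <- integer(0)
  for (w in expand_iupac(iupac)) {
    m <- gregexpr(paste0("(?=", w, ")"), sequence, perl = TRUE)[[1]]
    offs <- c(offs, m[m > 0] - 1L)
  }
  sort(unique(offs))
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Gap-length-enumeration alignment oracle: a different recurrence from the
# three-state Gotoh DP (gaps of every length considered explicitly)
oracle_global_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                                match = 5, mismatch = -4) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  S <- matrix(-Inf, la + 1, lb + 1)
  S[1, 1] <- 0
  for (i in 0:la) {
    for (j in 0:lb) {
      if (i == 0 && j == 0) next
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
        best <- max(best, S[i, j] + s)
      }
      if (i > 0) {
        g <- 1:i
        best <- max(best, max(S[i - g + 1, j + 1] - (gap_open + g * gap_extend)))
      }
      if (j > 0) {
        g <- 1:j
        best <- max(best, max(S[i + 1, j - g + 1] - (gap_open + g * gap_extend)))
      }
      S[i + 1, j + 1] <- best
    }
  }
  S[la + 1, lb + 1]
}

# Per-base set-intersection overlap oracle
oracle_overlaps <- function(query, ann, min_overlap = 1) {
  qb <- seq(query$start + 1L, query$end)
  hits <- 0L
  for (k in seq_len(nrow(ann))) {
    if (ann$chrom[k] != query$chrom) next
    ab <- seq(ann$start[k] + 1L, ann$end[k])
    if (length(intersect(qb, ab)) >= min_overlap) return(TRUE)
  }
  FALSE
}

# Exact two-sided hypergeometric p (probability-mass rule) for a 2x2 table
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# substitute a fraction d of bases (always to a different base)
mutate_seq <- function(s, d) {
  ch <- strsplit(s, "")[[1]]
  i <- which(stats::runif(length(ch)) < d)
  ch[i] <- vapply(ch[i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}
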