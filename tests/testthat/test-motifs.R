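test_that("pattern construction validates the IUPAC alphabet", {
  expect_error(motif_pattern("x", "TKAZ"), "invalid IUPAC")
  expect_error(motif_pattern("x", "TKA"), "length")
  p <- motif_pattern("AP-1", "TKASTMA", "AP-1")
  expect_s3_class(p, "motif_pattern")
})

test_that("scanner handles the worked AP-1 cases and empty input", {
  ap1 <- registry_pattern("AP-1")
  expect_equal(scan_motif("", ap1)$c, 0)
  h <- scan_motif("TGACTCA", ap1, "forward")
  expect_equal(h$c, 1)
  expect_equal(h$positions$offset, 0L)
  expect_equal(scan_motif("TGACTCATGACTCA", ap1, "both_dedup")$c, 2)
})

test_that("scanner equals the word-expansion oracle on random sequences", {
  reg <- motif_registry()
  set.seed(101)
  seqs <- replicate(12, random_seq(2000))
  for (k in seq_len(nrow(reg))) {
    pat <- motif_pattern(reg$name[k], reg$iupac[k], reg$family[k])
    for (s in seqs[seq_len(3)]) {
      got <- scan_motif(s, pat, "forward")$positions$offset
      expect_identical(got, oracle_scan_offsets(s, reg$iupac[k]),
                       info = reg$name[k])
    }
  }
  # strand modes against the oracle run on both strands
  ets <- registry_pattern("ETS")
  for (s in seqs) {
    fwd <- oracle_scan_offsets(s, ets$iupac)
    rev <- oracle_scan_offsets(s, iupac_reverse_complement(ets$iupac))
    expect_equal(scan_motif(s, ets, "both_dedup")$c,
                 length(union(fwd, rev)))
    expect_equal(scan_motif(s, ets, "both_sum")$c,
                 length(fwd) + length(rev))
  }
})

test_that("AP-1 consensus is a degenerate palindrome, ETS is not", {
  expect_equal(iupac_reverse_complement("TKASTMA"), "TKASTMA")
  expect_false(iupac_reverse_complement("VVGGAWVY") == "VVGGAWVY")
  ap1 <- registry_pattern("AP-1")
  set.seed(11)
  for (r in 1:10) {
    s <- random_seq(1000)
    expect_equal(scan_motif(s, ap1, "both_dedup")$c,
                 scan_motif(s, ap1, "forward")$c)
  }
})

test_that("N in the subject matches only an N pattern position", {
  ap1 <- registry_pattern("AP-1")       # TKASTMA, no N positions
  expect_equal(scan_motif("TGANTCA", ap1, "forward")$c, 0)
  fos <- registry_pattern("FOS")        # TKANTYA has an N position
  expect_equal(scan_motif("TGANTCA", fos, "forward")$c, 1)
  expect_equal(scan_motif("TGACTCA", fos, "forward")$c, 1)
})

test_that("per-kb frequency follows f = 1000c/s", {
  expect_equal(motif_frequency(6, 800), 7.5)
  expect_equal(motif_frequency(3, 459), 6.536, tolerance = 1e-3)
  expect_equal(motif_frequency(0, 123), 0)
  expect_error(motif_frequency(1, 0), "s must be")
  # linear in c, inverse in s
  expect_equal(motif_frequency(10, 500), 2 * motif_frequency(5, 500))
  expect_equal(motif_frequency(5, 1000), motif_frequency(5, 500) / 2)
})

test_that("registry carries the 21 per-factor codes plus two family codes", {
  reg <- motif_registry()
  expect_equal(nrow(reg), 23)
  expect_equal(sum(!reg$consensus), 21)
  expect_equal(sum(reg$family == "ETS" & !reg$consensus), 14)
  expect_equal(sum(reg$family == "AP-1" & !reg$consensus), 7)
  expect_equal(registry_pattern("JUN")$iupac, "TGASTCA")
  expect_error(registry_pattern("nope"), "unknown")
})

test_that("motif-group classification partitions constructed regions", {
  # backgrounds of T runs carry neither motif; plant known words
  pad <- strrep("T", 40)
  seqs <- c(ap1_only = paste0(pad, "TGACTCA", pad),
            ets_only = paste0(pad, "AAGGAAAC", pad),
            both = paste0(pad, "TGACTCA", pad, "AAGGAAAC", pad),
            neither = paste0(pad, pad))
  genome <- stats::setNames(as.character(seqs), names(seqs))
  regions <- genomic_intervals(names(genome), 0,
                               nchar(genome), name = names(genome))
  cls <- classify_motif_groups(regions, genome)
  expect_equal(unname(cls$counts),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(cls$counts), nrow(regions))
  empty <- classify_motif_groups(regions[0, ], genome)
  expect_equal(sum(empty$counts), 0L)
})

test_that("GC-matched background reproduces the target GC histogram", {
  set.seed(3)
  chrom <- random_seq(60000, gc = 0.5)
  genome <- c(chr1 = chrom)
  starts <- seq(0, 59000, by = 500)
  pool <- genomic_intervals("chr1", starts, starts + 400)
  targets <- pool[sample.int(nrow(pool), 30), ]
  bg <- gc_matched_background(pool, targets, genome, n = 30,
                              gc_tolerance = 0.05, seed = 5)
  expect_equal(nrow(bg), 30)
  binify <- function(x) findInterval(gc_content(region_sequences(x, genome)),
                                     seq(0, 1.05, by = 0.05),
                                     rightmost.closed = TRUE)
  expect_equal(sort(table(binify(bg))), sort(table(binify(targets))))
  # deterministic under seed
  bg2 <- gc_matched_background(pool, targets, genome, n = 30,
                               gc_tolerance = 0.05, seed = 5)
  expect_identical(bg, bg2)
  # an all-AT pool cannot match GC-rich targets: errors naming the bin
  at_genome <- c(chr1 = strrep("AT", 30000))
  expect_error(gc_matched_background(pool, targets, at_genome,
                                     n = 30, gc_tolerance = 0.05, seed = 1,
                                     target_genome = genome),
               "GC bin")
})

test_that("presence enrichment reproduces exact hypergeometric p-values", {
  # construct sequences with/without the AP-1 word
  with_m <- paste0(strrep("T", 20), "TGACTCA", strrep("T", 20))
  without <- strrep("T", 47)
  mkgenome <- function(n_with_f, n_f, n_with_b, n_b) {
    seqs <- c(rep(with_m, n_with_f), rep(without, n_f - n_with_f),
              rep(with_m, n_with_b), rep(without, n_b - n_with_b))
    stats::setNames(seqs, sprintf("s%02d", seq_along(seqs)))
  }
  genome <- mkgenome(8, 10, 2, 10)
  regions <- genomic_intervals(names(genome), 0, nchar(genome))
  fore <- regions[1:10, ]; back <- regions[11:20, ]
  res <- motif_presence_enrichment(fore, back, genome,
                                   registry_pattern("AP-1"))
  expect_equal(res$fore_present, 8)
  expect_equal(res$back_present, 2)
  expect_equal(res$p_value, oracle_fisher_p(8, 2, 2, 8), tolerance = 1e-9)
  expect_equal(res$p_value, 0.023, tolerance = 0.002)

  genome2 <- mkgenome(10, 10, 0, 10)
  regions2 <- genomic_intervals(names(genome2), 0, nchar(genome2))
  res2 <- motif_presence_enrichment(regions2[1:10, ], regions2[11:20, ],
                                    genome2, registry_pattern("AP-1"))
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  # equal proportions give odds ratio 1
  genome3 <- mkgenome(5, 10, 5, 10)
  regions3 <- genomic_intervals(names(genome3), 0, nchar(genome3))
  res3 <- motif_presence_enrichment(regions3[1:10, ], regions3[11:20, ],
                                    genome3, registry_pattern("AP-1"))
  expect_equal(res3$odds_ratio, 1)
  expect_error(motif_presence_enrichment(regions3[0, ], regions3, genome3,
                                         registry_pattern("AP-1")),
               "non-empty")
})

test_that("enrichment p-values are uniform under the null", {
  set.seed(23)
  # fore and back drawn from one pool: presence counts are exchangeable
  n <- 500
  pvals <- numeric(n)
  for (r in seq_len(n)) {
    pres <- stats::rbinom(2, 12, 0.4)
    pvals[r] <- stats::fisher.test(matrix(c(pres[1], 12 - pres[1],
                                            pres[2], 12 - pres[2]), 2,
                                          byrow = TRUE))$p.value
  }
  # discrete p-values are stochastically >= uniform; check no excess of
  # small values at two cutoffs
  expect_lt(mean(pvals < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
  expect_lt(mean(pvals < 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / n))
})

test_that("relative overlap ratio follows its definition and detects planted association", {
  # constructed curve: n0 = 25 of the zero-bin overlap, bin1 has 50
  chrlen <- c(c1 = 1000000L)
  starts <- seq(0, 149000, by = 1000)[1:150]
  regions <- genomic_intervals("c1", starts, starts + 1000)
  regions$frequency <- rep(c(0, 3), times = c(100, 50))
  # peaks cover 25 of the zero-frequency and all 50 of the dense regions
  cover <- c(sample(1:100, 25), 101:150)
  peaks <- genomic_intervals("c1", starts[cover] + 100, starts[cover] + 300)
  curve <- relative_overlap_ratio(regions, peaks, bins = c(Inf),
                                  chrom_lengths = chrlen, seed = 2)
  expect_equal(curve$true$r[curve$true$bin == 0], 1)
  expect_equal(curve$true$r[curve$true$bin == 1], 2)
  # shuffled control has no association: ratio near the bin-size ratio
  expect_lt(curve$shuffled$r[curve$shuffled$bin == 1], 1.5)
  # planted association: r non-decreasing in the frequency bin
  expect_true(all(diff(curve$true$r) >= 0))
  # empty reference bin errors
  none <- genomic_intervals("c1", 900000, 901000)
  expect_error(relative_overlap_ratio(regions, none, bins = c(Inf),
                                      chrom_lengths = chrlen, seed = 2),
               "empty reference bin")
})
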