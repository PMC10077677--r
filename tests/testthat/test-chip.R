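make_track <- function(chrom, start, end, value) {
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

test_that("region counting sums per-base coverage", {
  track <- make_track("chr1", 0, 1000, 2.0)
  regions <- genomic_intervals("chr1", c(100, 400), c(200, 450))
  expect_equal(region_counts(track, regions), c(200, 100))
  # zero track
  expect_equal(region_counts(make_track("chr1", 0, 1000, 0), regions),
               c(0, 0))
  # additivity over disjoint regions
  joint <- genomic_intervals("chr1", 100, 450)
  parts <- genomic_intervals("chr1", c(100, 200, 400), c(200, 400, 450))
  tr <- make_track("chr1", c(0, 300), c(300, 1000), c(1.5, 3))
  expect_equal(sum(region_counts(tr, parts)), region_counts(tr, joint))
  # clipping warns when chromosome bounds are known
  expect_warning(region_counts(track, genomic_intervals("chr1", 900, 1100),
                               chrom_lengths = c(chr1 = 1000)), "clipped")
})

test_that("count table validates its invariants", {
  regions <- genomic_intervals("c", c(0, 1000), c(500, 1500))
  counts <- matrix(5L, 2, 4)
  expect_error(region_count_table(regions, counts, rep("injured", 4),
                                  lib_size = c(1, 1, 1, 1)),
               "library size")
  expect_error(region_count_table(regions, counts - 10L,
                                  rep(c("control", "injured"), 2)),
               "non-negative")
  tab <- region_count_table(regions, counts,
                            rep(c("control", "injured"), each = 2))
  expect_s3_class(tab, "region_count_table")
})

test_that("identical conditions yield no differential calls", {
  set.seed(9)
  regions <- genomic_intervals("c", seq(0, 99 * 2000, by = 2000),
                               seq(0, 99 * 2000, by = 2000) + 1000)
  base <- rnbinom(100, size = 10, mu = 80)
  counts <- cbind(base, base, base, base)
  tab <- region_count_table(regions, counts,
                            rep(c("control", "injured"), each = 2),
                            lib_size = rep(50000, 4))
  d <- call_differential_regions(tab, alpha = 0.5)
  expect_equal(sum(d$call == "IRE"), 0)
  expect_true(all(d$log2fc == 0))
})

test_that("scaling injured counts never decreases a fold change", {
  set.seed(10)
  counts <- matrix(rnbinom(400, size = 10, mu = 60), ncol = 4)
  regions <- genomic_intervals("c", seq(0, 99) * 2000, seq(0, 99) * 2000 + 900)
  cond <- rep(c("control", "injured"), each = 2)
  lib <- rep(1e5, 4)
  t1 <- region_count_table(regions, counts, cond, lib_size = lib)
  scaled <- counts
  scaled[, 3:4] <- scaled[, 3:4] * 3L
  t2 <- region_count_table(regions, scaled, cond, lib_size = lib)
  d1 <- call_differential_regions(t1)
  d2 <- call_differential_regions(t2)
  expect_true(all(d2$log2fc >= d1$log2fc))
})

test_that("differential calls are invariant to rescaling all library sizes", {
  set.seed(12)
  counts <- matrix(rnbinom(400, size = 10, mu = 60), ncol = 4)
  regions <- genomic_intervals("c", seq(0, 99) * 2000, seq(0, 99) * 2000 + 900)
  cond <- rep(c("control", "injured"), each = 2)
  t1 <- region_count_table(regions, counts, cond, lib_size = rep(1e5, 4))
  t2 <- region_count_table(regions, counts, cond, lib_size = rep(7e5, 4))
  d1 <- call_differential_regions(t1)
  d2 <- call_differential_regions(t2)
  expect_equal(d1$log2fc, d2$log2fc)
  expect_equal(d1$p_value, d2$p_value)
})

test_that("planted injury-responsive regions are recovered", {
  # reduced version of the acceptance-scale simulation
  fc <- c(rep(4, 60), rep(1, 300))
  tab <- simulate_chip_counts(config = sim_config(seed = 21),
                              n_regions = 360, fold_changes = fc, seed = 21)
  d <- call_differential_regions(tab, fc_threshold = 1.5, alpha = 0.05,
                                 criterion = "fdr")
  called <- d$call == "IRE"
  expect_gte(mean(called[1:60]), 0.85)
  expect_lte(sum(called[61:360]) / max(1, sum(called)), 0.1)
})

test_that("single-replicate designs fall back to Poisson with a warning", {
  regions <- genomic_intervals("c", c(0, 2000), c(1000, 3000))
  counts <- matrix(c(50L, 60L, 55L, 65L), 2, 2)
  tab <- region_count_table(regions, counts, c("control", "injured"),
                            lib_size = c(1e4, 1e4))
  expect_warning(d <- call_differential_regions(tab), "Poisson")
  expect_equal(attr(d, "dispersion"), 0)
})

test_that("IRE definition excludes promoter-proximal up-called peaks", {
  genes <- gene_models("g1", "c", "+", 5000)
  # peak A distal+up, peak B proximal+up, peak C distal flat
  regions <- genomic_intervals("c", c(20000, 4000, 40000),
                               c(21000, 5000, 41000),
                               name = c("A", "B", "C"))
  counts <- rbind(c(40, 45, 200, 210), c(40, 45, 200, 210),
                  c(100, 110, 100, 105))
  tab <- region_count_table(regions, counts,
                            rep(c("control", "injured"), each = 2),
                            lib_size = rep(1e5, 4))
  d <- call_differential_regions(tab, alpha = 0.1)
  res <- define_ires(d, genes, flank = 2000)
  expect_equal(res$class[res$name == "A"], "IRE")
  expect_equal(res$class[res$name == "B"], "excluded")
  expect_equal(res$class[res$name == "C"], "non-IRE")
  # partition is exhaustive
  expect_equal(sum(table(res$class)), nrow(res))
})

test_that("signal matrix matches a naive per-base oracle", {
  set.seed(31)
  track <- make_track("chr1", seq(0, 19000, by = 1000),
                      seq(1000, 20000, by = 1000), round(runif(20, 0, 5), 2))
  anchors <- genomic_intervals("chr1", c(4000, 9000, 13500),
                               c(6000, 11000, 14500))
  sm <- signal_matrix(track, anchors, flank = 2000, bin = 250,
                      chrom_lengths = c(chr1 = 20000))
  expect_equal(dim(sm$values), c(3, 16))
  # per-base oracle
  base_val <- rep(0, 20000)
  for (k in seq_len(nrow(track))) {
    base_val[(track$start[k] + 1):track$end[k]] <-
      base_val[(track$start[k] + 1):track$end[k]] + track$value[k]
  }
  mids <- interval_midpoint(anchors)
  for (i in 1:3) {
    for (j in 1:16) {
      lo <- mids[i] - 2000 + (j - 1) * 250
      expect_equal(sm$values[i, j], mean(base_val[(lo + 1):(lo + 250)]),
                   info = paste(i, j))
    }
  }
})

test_that("signal matrix is constant on constant tracks and flips minus strands", {
  track <- make_track("chr1", 0, 50000, 3.5)
  anchors <- genomic_intervals("chr1", c(10000, 20000), c(11000, 21000))
  sm <- signal_matrix(track, anchors, flank = 1000, bin = 100)
  expect_true(all(sm$values == 3.5))
  # ramp track read at a minus-strand TSS is reversed
  ramp <- make_track("chr1", seq(0, 29900, by = 100),
                     seq(100, 30000, by = 100), seq_len(300))
  genes <- gene_models(c("p", "m"), "chr1", c("+", "-"), c(15000, 15000))
  smg <- signal_matrix(ramp, genes, flank = 1000, bin = 100)
  expect_equal(smg$values[2, ], rev(smg$values[1, ]))
})

test_that("planted central peak maximizes the metagene profile centrally", {
  # triangular peak centered on the anchor
  pos <- seq(0, 1990, by = 10)
  height <- pmax(0, 100 - abs(pos + 5 - 1000) / 5)
  track <- make_track("chr1", pos, pos + 10, height)
  anchor <- genomic_intervals("chr1", 900, 1100)
  sm <- signal_matrix(track, anchor, flank = 500, bin = 100,
                      chrom_lengths = c(chr1 = 2000))
  prof <- sm$profile
  expect_true(which.max(prof) %in% c(5, 6))
})

test_that("enhancer states are recovered and named by the signal rule", {
  set.seed(71)
  n <- 40
  mk <- function(mu) matrix(rnorm(n * 10, mu, 0.5), n, 10)
  ac <- rbind(mk(1), mk(1), mk(10))    # poised, primed, active
  me3 <- rbind(mk(10), mk(1), mk(1))
  smac <- structure(list(values = ac), class = "signal_matrix")
  smme <- structure(list(values = me3), class = "signal_matrix")
  labels <- classify_enhancer_states(smac, smme, seed = 7)
  truth <- rep(c("poised", "primed", "active"), each = n)
  expect_equal(labels, truth)
  # permuting rows permutes labels identically
  perm <- sample(3 * n)
  smac2 <- structure(list(values = ac[perm, ]), class = "signal_matrix")
  smme2 <- structure(list(values = me3[perm, ]), class = "signal_matrix")
  expect_equal(classify_enhancer_states(smac2, smme2, seed = 7),
               truth[perm])
  expect_error(classify_enhancer_states(
    structure(list(values = ac[1:2, ]), class = "signal_matrix"),
    structure(list(values = me3[1:2, ]), class = "signal_matrix"), k = 3),
    "exceeds")
})

test_that("conservation window means exclude missing bases", {
  regions <- genomic_intervals("chr1", 4500, 5500)  # midpoint 5000
  # constant score
  expect_equal(conservation_window_mean(
    make_track("chr1", 0, 10000, 0.5), regions), 0.5)
  # half covered at 1.0, half missing: missing bases are excluded
  expect_equal(conservation_window_mean(
    make_track("chr1", 4500, 5000, 1.0), regions), 1.0)
  # linear ramp: mean equals the midpoint value
  pos <- seq(4000, 5990, by = 10)
  ramp <- make_track("chr1", pos, pos + 10, (pos - 4000) / 10)
  got <- conservation_window_mean(ramp, regions, window = 1000)
  expect_equal(got, mean(c((4500 - 4000) / 10, (5490 - 4000) / 10)),
               tolerance = 0.01)
  # fully missing window is NA, not zero
  expect_true(is.na(conservation_window_mean(
    make_track("chr1", 20000, 21000, 1), regions)))
  expect_error(conservation_window_mean(ramp, regions, window = 999),
               "even")
})
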