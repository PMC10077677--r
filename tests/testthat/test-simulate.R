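small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_chrom = 1, chrom_length = 6e5, n_genes = 30,
             n_enhancers = 24, ...)
}

test_that("generation is deterministic and files are byte-identical", {
  cfg <- small_cfg(seed = 81)
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$enhancers, s2$enhancers)
  expect_identical(s1$orthologs, s2$orthologs)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("planted motifs are recovered by the scanner (self-consistency)", {
  sim <- simulate_genome_pair(small_cfg(seed = 82,
                                        motifs_ire = c(ap1 = 1, ets = 3)))
  tab <- sim$enhancers$a
  seqs <- region_sequences(tab, sim$genomes$a)
  ets <- registry_pattern("ETS"); ap1 <- registry_pattern("AP-1")
  for (i in seq_len(nrow(tab))) {
    expect_gte(scan_motif(seqs[i], ets)$c, tab$ets_planted[i])
    expect_gte(scan_motif(seqs[i], ap1)$c, tab$ap1_planted[i])
  }
  # IRE class got the configured planted counts
  expect_true(all(tab$ets_planted[tab$class == "IRE"] == 3))
  expect_true(all(tab$ap1_planted[tab$class == "IRE"] == 1))
})

test_that("enhancers sit 2-100 kb from their host TSS", {
  sim <- simulate_genome_pair(small_cfg(seed = 83))
  tab <- sim$enhancers$a
  tss <- sim$genes$a$tss[match(tab$gene_id, sim$genes$a$gene_id)]
  mid <- interval_midpoint(tab)
  d <- abs(mid - tss)
  expect_true(all(d >= 2000))
  expect_true(all(d <= 100000))
})

test_that("ablated copies lose the family motifs, conserved copies keep them", {
  sim <- simulate_genome_pair(small_cfg(seed = 84, divergence = 0,
                                        ablation_prob = 0.5))
  cross <- sim$truth$cross
  tab <- sim$enhancers$a
  ets <- registry_pattern("ETS"); ap1 <- registry_pattern("AP-1")
  seqs_a <- region_sequences(tab, sim$genomes$a)
  for (i in which(!is.na(cross$partner_start))) {
    partner <- genomic_intervals(cross$partner_chrom[i],
                                 cross$partner_start[i],
                                 cross$partner_end[i])
    pseq <- region_sequences(partner, sim$genomes$b)
    found_a <- scan_motif(seqs_a[i], ets)$c + scan_motif(seqs_a[i], ap1)$c
    found_b <- scan_motif(pseq, ets)$c + scan_motif(pseq, ap1)$c
    if (isTRUE(cross$ablated[i])) {
      # at zero divergence the copy differs only in the scrambled spans
      expect_lt(found_b, found_a)
    } else if (cross$cross_class[i] == "shared") {
      expect_equal(found_b, found_a)
    }
  }
})

test_that("zero divergence without ablation makes every orthologous IRE shared", {
  sim <- simulate_genome_pair(small_cfg(seed = 85, divergence = 0,
                                        ablation_prob = 0))
  cross <- sim$truth$cross
  tab <- sim$enhancers$a
  idx <- which(tab$class == "IRE" & cross$cross_class != "unmapped")
  expect_true(all(cross$cross_class[idx] == "shared"))
  # end-to-end: the cross-species module recovers the planted classes
  a2b <- stats::setNames(sim$orthologs$target_gene_id,
                         sim$orthologs$query_gene_id)
  b_ires <- sim$enhancers$b[sim$enhancers$b$class == "IRE", ]
  take <- idx[seq_len(min(4, length(idx)))]
  mapped <- lapply(take, function(i) {
    tg <- sim$genes$b[sim$genes$b$gene_id == a2b[[tab$gene_id[i]]], ]
    map_orthologous_sequence(tab[i, ], sim$genomes$a, tg, sim$genomes$b,
                             window = 100000)$interval
  })
  cls <- classify_cross_species_ires(tab[take, ], mapped, b_ires)
  expect_true(all(cls == "shared"))
})

test_that("chip count simulation approaches the Poisson limit as phi -> 0", {
  cfg <- sim_config(seed = 86, dispersion = 1e-6, replicates = 30,
                    depth = 100)
  tab <- simulate_chip_counts(config = cfg, n_regions = 200,
                              fold_changes = rep(1, 200), seed = 86)
  ctl <- tab$counts[, tab$sample_meta$condition == "control"]
  ratio <- apply(ctl, 1, var) / rowMeans(ctl)
  # variance/mean ratio concentrates near 1
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("a null ChIP configuration produces no excess IRE calls", {
  tab <- simulate_chip_counts(config = sim_config(seed = 87),
                              n_regions = 1000,
                              fold_changes = rep(1, 1000), seed = 87)
  d <- call_differential_regions(tab, alpha = 0.05)
  expect_lte(sum(d$call == "IRE"), 0.05 * 1000)
  rate <- mean(d$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("RNA simulation is deterministic and recovers planted induction", {
  sim <- simulate_genome_pair(small_cfg(seed = 88, rna_induced_fc = 4))
  r1 <- simulate_rna_counts(sim)
  r2 <- simulate_rna_counts(sim)
  expect_identical(r1$counts, r2$counts)
  de <- differential_expression(r1$counts, r1$condition,
                                fc_threshold = 1.5, alpha = 0.1)
  induced <- r1$truth$induced
  if (sum(induced) >= 5) {
    expect_gte(mean(de$significant[induced]), 0.7)
  }
  fp <- sum(de$significant & !induced)
  expect_lte(fp / max(1, sum(de$significant)), 0.2)
  # TPM of a non-induced gene varies only by sampling noise across samples
  # (NB cv at dispersion 0.1 and depth ~50 is about 0.35)
  tp <- tpm(r1$counts, r1$lengths)
  flat <- which(!induced)
  cv <- apply(tp[flat, , drop = FALSE], 1, function(x) sd(x) / mean(x))
  expect_lt(median(cv), 0.7)
})

test_that("scRNA simulation is deterministic; no induction means chance accuracy", {
  cfg <- sim_config(seed = 89)
  s1 <- simulate_sc_counts(cfg)
  s2 <- simulate_sc_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  # negative control: flat injury response -> assignments at chance level
  cfg0 <- sim_config(seed = 90, sc_induced_fc = 1)
  s0 <- simulate_sc_counts(cfg0)
  asg <- assign_cell_types(s0$counts, s0$cell_meta, s0$truth$gene_id)
  acc <- mean(asg$assignment$cell_type == s0$truth$true_type)
  # 5 types: chance is 0.2; allow generous sampling noise on 50 genes
  expect_lt(acc, 0.45)
})

test_that("infeasible configurations error at generation", {
  expect_error(simulate_genome_pair(
    sim_config(seed = 91, n_chrom = 1, chrom_length = 3e5, n_genes = 500)),
    "infeasible")
  expect_error(sim_config(seed = 1, ire_fraction = 1.2), "fractions")
  expect_error(sim_config(), "seed")
})
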