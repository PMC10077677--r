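# Two-species synthetic data with planted ground truth.
#
# The generator emulates the statistical structure of the real inputs: two
# genomes with an orthology map, enhancers planted 2-100 kb from gene TSSs
# with controlled AP-1/ETS motif content, orthologous enhancer copies at
# controlled divergence (optionally with motif ablation, which removes
# injury-responsiveness in the second species), replicated
# negative-binomial ChIP counts with planted fold changes, bulk RNA counts
# with induction of IRE-linked genes, and an scRNA matrix with
# type-restricted induction. Background sequence is i.i.d. at a fixed GC;
# repeat structure and mappability are deliberately not modelled.

#' Simulation configuration
#'
#' Defaults are sized so that a full genome pair generates in well under a
#' minute: 2 chromosomes of 2 Mb per species, 200 genes, 300 enhancers.
#'
#' @param seed mandatory integer RNG seed.
#' @param n_chrom,chrom_length,gc chromosomes per species, their length
#'   (bp), background GC fraction.
#' @param n_genes,n_enhancers genes and enhancers per species.
#' @param enhancer_length planted enhancer length (bp).
#' @param ire_fraction fraction of enhancers that are injury-responsive.
#' @param motifs_ire,motifs_nonire planted AP-1/ETS motif counts per
#'   enhancer class, named vectors `c(ap1 = , ets = )`.
#' @param fc_range injury fold-change range for planted IREs (uniform).
#' @param dispersion NB dispersion of ChIP/RNA counts.
#' @param replicates replicates per condition.
#' @param depth expected baseline ChIP count per region.
#' @param ortholog_fraction fraction of species-A genes with an ortholog.
#' @param divergence per-base substitution probability of orthologous
#'   enhancer copies.
#' @param ablation_prob probability that a diverged copy has its planted
#'   motifs scrambled (creating a species-specific IRE).
#' @param rna_depth expected baseline RNA count per gene.
#' @param rna_induced_fc fold change of induced (IRE-linked) genes.
#' @param sc_genes,sc_types,sc_cells_per_type,sc_induced_fc scRNA matrix
#'   shape: number of genes, cell types used (from [CELL_TYPES]), cells per
#'   type and condition, and induction fold change in the true type.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chrom = 2L, chrom_length = 2e6, gc = 0.42,
                       n_genes = 200L, n_enhancers = 300L,
                       enhancer_length = 1000L,
                       ire_fraction = 0.4,
                       motifs_ire = c(ap1 = 1, ets = 3),
                       motifs_nonire = c(ap1 = 0, ets = 1),
                       fc_range = c(3, 6),
                       dispersion = 0.1,
                       replicates = 2L,
                       depth = 100,
                       ortholog_fraction = 0.7,
                       divergence = 0.05,
                       ablation_prob = 0.5,
                       rna_depth = 50,
                       rna_induced_fc = 3,
                       sc_genes = 50L, sc_types = 5L,
                       sc_cells_per_type = 100L, sc_induced_fc = 4) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length), gc = gc,
              n_genes = as.integer(n_genes),
              n_enhancers = as.integer(n_enhancers),
              enhancer_length = as.integer(enhancer_length),
              ire_fraction = ire_fraction,
              motifs_ire = motifs_ire, motifs_nonire = motifs_nonire,
              fc_range = fc_range, dispersion = dispersion,
              replicates = as.integer(replicates), depth = depth,
              ortholog_fraction = ortholog_fraction,
              divergence = divergence, ablation_prob = ablation_prob,
              rna_depth = rna_depth, rna_induced_fc = rna_induced_fc,
              sc_genes = as.integer(sc_genes),
              sc_types = as.integer(sc_types),
              sc_cells_per_type = as.integer(sc_cells_per_type),
              sc_induced_fc = sc_induced_fc)
  fracs <- c(cfg$gc, cfg$ire_fraction, cfg$ortholog_fraction,
             cfg$divergence, cfg$ablation_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (cfg$chrom_length <= 0) stop("chromosome length must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' Fields present in the file override the [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return A `sim_config` list.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

random_genome <- function(n_chrom, chrom_length, gc, prefix) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- lapply(seq_len(n_chrom), function(i)
    sample(names(p), chrom_length, replace = TRUE, prob = p))
  names(chroms) <- paste0(prefix, "chr", seq_len(n_chrom))
  chroms
}

# uniformly sample one concrete realization of an IUPAC code
realize_iupac <- function(iupac) {
  letters <- strsplit(iupac, "")[[1]]
  paste(vapply(letters, function(l) {
    allowed <- setdiff(IUPAC_SETS[[l]], "N")
    allowed[sample.int(length(allowed), 1)]
  }, character(1)), collapse = "")
}

# scramble the bases of a motif occurrence until no family-consensus match
# overlaps the scrambled span (the ablation model); matches elsewhere in
# the window (e.g. neighbouring planted motifs) are left alone
scramble_motif <- function(chars, start0, len, patterns) {
  win_lo0 <- max(0L, start0 - 12L)  # 0-based window start
  for (try in 1:200) {
    idx <- (start0 + 1L):(start0 + len)
    chars[idx] <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    win_hi <- min(length(chars), start0 + len + 12L)
    win <- paste(chars[(win_lo0 + 1L):win_hi], collapse = "")
    overlapping <- FALSE
    for (p in patterns) {
      hits <- scan_motif(win, p, "both_dedup")$positions
      if (nrow(hits) == 0) next
      abs_start <- win_lo0 + hits$offset
      w <- nchar(p$iupac)
      if (any(abs_start < start0 + len & abs_start + w > start0)) {
        overlapping <- TRUE
        break
      }
    }
    if (!overlapping) return(chars)
  }
  stop("failed to ablate motif")
}

place_genes <- function(cfg, chrom_names, prefix) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chrom)
  margin <- 110000L  # room for a +/-100 kb enhancer neighbourhood
  usable <- cfg$chrom_length - 2L * margin
  slot <- floor(usable / per_chrom)
  if (slot < 1000L) stop("infeasible placement: too many genes for length")
  gene_id <- character(0); chrom <- character(0); tss <- integer(0)
  k <- 0L
  for (ci in seq_len(cfg$n_chrom)) {
    n_here <- min(per_chrom, cfg$n_genes - k)
    if (n_here <= 0) break
    offs <- margin + slot * (seq_len(n_here) - 1L) +
      sample.int(max(1L, slot %/% 2L), n_here, replace = TRUE)
    gene_id <- c(gene_id, sprintf("%sgene%03d", prefix, k + seq_len(n_here)))
    chrom <- c(chrom, rep(chrom_names[ci], n_here))
    tss <- c(tss, as.integer(offs))
    k <- k + n_here
  }
  gene_models(gene_id, chrom, sample(c("+", "-"), length(gene_id),
                                     replace = TRUE), tss)
}

plant_enhancer <- function(chars, enh_start0, cfg, n_ap1, n_ets) {
  # non-overlapping motif offsets within the enhancer
  len <- cfg$enhancer_length
  motifs <- c(rep("AP-1", n_ap1), rep("ETS", n_ets))
  placed <- data.frame(family = character(0), offset = integer(0),
                       width = integer(0), stringsAsFactors = FALSE)
  taken <- integer(0)
  for (fam in motifs) {
    word <- realize_iupac(motif_registry(consensus_only = TRUE)$iupac[
      motif_registry(consensus_only = TRUE)$name == fam])
    w <- nchar(word)
    for (try in 1:200) {
      off <- sample.int(len - w + 1L, 1L) - 1L  # 0-based within enhancer
      span <- off:(off + w - 1L)
      if (!any(span %in% taken)) break
    }
    taken <- c(taken, span)
    idx <- enh_start0 + off + seq_len(w)
    chars[idx] <- strsplit(word, "")[[1]]
    placed <- rbind(placed, data.frame(family = fam, offset = off,
                                       width = w, stringsAsFactors = FALSE))
  }
  list(chars = chars, motifs = placed)
}

#' Simulate a two-species genome pair with planted ground truth
#'
#' Generates species-A and species-B genomes (i.i.d. background at the
#' configured GC), gene models, enhancers planted 2-100 kb from their
#' gene's TSS with class-controlled AP-1/ETS motif content, an ortholog
#' table, and orthologous enhancer copies in species B at the configured
#' divergence. A diverged copy of a species-A IRE either remains injury
#' responsive in B (a shared IRE) or has its planted motifs scrambled
#' (ablated) and loses responsiveness (a species-A-specific IRE). Species B
#' additionally carries its own B-specific IREs at non-orthologous genes.
#' Everything planted is recorded in `truth`.
#'
#' @param config a [sim_config()].
#' @return An `ire_simulation` list: `genomes` (named character per
#'   species), `genes`, `enhancers` (interval data.frames with class and
#'   planted annotations), `orthologs`, `truth` (incl. the per-IRE
#'   cross-species class), and `config`.
#' @export
simulate_genome_pair <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  reg <- motif_registry(consensus_only = TRUE)
  fam_patterns <- list(registry_pattern("AP-1"), registry_pattern("ETS"))

  genomes <- list(a = random_genome(cfg$n_chrom, cfg$chrom_length, cfg$gc, "a_"),
                  b = random_genome(cfg$n_chrom, cfg$chrom_length, cfg$gc, "b_"))
  genes_a <- place_genes(cfg, names(genomes$a), "a_")
  genes_b <- place_genes(cfg, names(genomes$b), "b_")

  # orthology: the first k A genes map onto the first k B genes (both in
  # randomized order), one target per query
  k <- round(cfg$ortholog_fraction * cfg$n_genes)
  a_orth <- sample(genes_a$gene_id, k)
  b_orth <- sample(genes_b$gene_id, k)
  orthologs <- data.frame(query_gene_id = a_orth, target_gene_id = b_orth,
                          pct_identity = round(stats::runif(k, 60, 100), 1),
                          stringsAsFactors = FALSE)
  genes_a$ortholog_id[match(a_orth, genes_a$gene_id)] <- b_orth
  genes_b$ortholog_id[match(b_orth, genes_b$gene_id)] <- a_orth

  # species A enhancers
  enh_a <- plant_species_enhancers(genomes$a, genes_a, cfg, "a_enh")
  genomes$a <- enh_a$genome
  tab_a <- enh_a$table

  # orthologous copies in B for enhancers of orthologous A genes
  cross <- data.frame(name = character(0), partner_chrom = character(0),
                      partner_start = integer(0), partner_end = integer(0),
                      divergence = numeric(0), ablated = logical(0),
                      cross_class = character(0), stringsAsFactors = FALSE)
  b_extra <- list()
  b_chars <- lapply(genomes$b, identity)
  occupied_b <- list()  # spans already written in B, per chromosome
  orth_map <- stats::setNames(orthologs$target_gene_id,
                              orthologs$query_gene_id)
  for (i in seq_len(nrow(tab_a))) {
    gene <- tab_a$gene_id[i]
    tgt_gene <- orth_map[gene]
    if (is.na(tgt_gene) || is.null(tgt_gene)) {
      cross <- rbind(cross, data.frame(
        name = tab_a$name[i], partner_chrom = NA_character_,
        partner_start = NA_integer_, partner_end = NA_integer_,
        divergence = NA_real_, ablated = NA,
        cross_class = "unmapped", stringsAsFactors = FALSE))
      next
    }
    g <- genes_b[genes_b$gene_id == tgt_gene, ]
    src_seq <- genomes$a[[tab_a$chrom[i]]][(tab_a$start[i] + 1L):tab_a$end[i]]
    # substitute at the configured per-base divergence (always to a
    # different base)
    nsub <- stats::rbinom(1, length(src_seq), cfg$divergence)
    if (nsub > 0) {
      pos <- sample.int(length(src_seq), nsub)
      src_seq[pos] <- vapply(src_seq[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    # place at a similar TSS offset in B, within the +/-100 kb window;
    # shift to a fresh offset if the preferred spot is already occupied
    offset <- tab_a$start[i] -
      genes_a$tss[genes_a$gene_id == gene]
    offset <- max(min(offset, 99000 - cfg$enhancer_length), -99000)
    clamp <- function(st) max(1000L, min(as.integer(st),
                                         cfg$chrom_length -
                                           cfg$enhancer_length - 1000L))
    b_start <- clamp(g$tss + offset)
    occ <- occupied_b[[g$chrom]]
    clashes <- function(st) {
      !is.null(occ) && any(st < occ[, 2] & st + cfg$enhancer_length > occ[, 1])
    }
    for (try in 1:200) {
      if (!clashes(b_start)) break
      alt <- sample(2000:(99000 - cfg$enhancer_length), 1) * sample(c(-1, 1), 1)
      b_start <- clamp(g$tss + alt)
    }
    occupied_b[[g$chrom]] <- rbind(occ, c(b_start,
                                          b_start + cfg$enhancer_length))
    chars <- b_chars[[g$chrom]]
    idx <- (b_start + 1L):(b_start + length(src_seq))
    chars[idx] <- src_seq
    ablate <- tab_a$class[i] == "IRE" && stats::runif(1) < cfg$ablation_prob
    if (ablate) {
      # scramble every planted motif occurrence of this enhancer copy
      pm <- enh_a$motifs[[tab_a$name[i]]]
      if (!is.null(pm) && nrow(pm) > 0) {
        for (r in seq_len(nrow(pm))) {
          chars <- scramble_motif(chars, b_start + pm$offset[r], pm$width[r],
                                  fam_patterns)
        }
      }
    }
    b_chars[[g$chrom]] <- chars
    shared <- tab_a$class[i] == "IRE" && !ablate
    if (shared) {
      b_extra[[length(b_extra) + 1]] <- data.frame(
        chrom = g$chrom, start = b_start,
        end = b_start + cfg$enhancer_length,
        name = paste0("b_", tab_a$name[i]), gene_id = tgt_gene,
        class = "IRE",
        fold_change = tab_a$fold_change[i], stringsAsFactors = FALSE)
    }
    cross <- rbind(cross, data.frame(
      name = tab_a$name[i], partner_chrom = g$chrom,
      partner_start = b_start,
      partner_end = b_start + cfg$enhancer_length,
      divergence = cfg$divergence, ablated = ablate,
      cross_class = if (tab_a$class[i] != "IRE") "non-IRE"
        else if (shared) "shared" else "a-specific",
      stringsAsFactors = FALSE))
  }
  genomes$b <- b_chars

  # species-B-only enhancers at genes without A orthologs
  own_b <- plant_species_enhancers(genomes$b, genes_b, cfg, "b_enh",
                                   only_genes = setdiff(genes_b$gene_id,
                                                        b_orth),
                                   occupied = occupied_b)
  genomes$b <- own_b$genome
  tab_b <- own_b$table
  if (length(b_extra) > 0) {
    shared_b <- do.call(rbind, b_extra)
    shared_b$ap1_planted <- tab_a$ap1_planted[match(sub("^b_", "",
                                                        shared_b$name),
                                                    tab_a$name)]
    shared_b$ets_planted <- tab_a$ets_planted[match(sub("^b_", "",
                                                        shared_b$name),
                                                    tab_a$name)]
    shared_b$strand <- "*"
    tab_b <- rbind(tab_b, shared_b[, names(tab_b)])
  }
  genomes$a <- lapply(genomes$a, paste, collapse = "")
  genomes$b <- lapply(genomes$b, paste, collapse = "")
  structure(list(
    genomes = list(a = unlist(genomes$a), b = unlist(genomes$b)),
    genes = list(a = genes_a, b = genes_b),
    enhancers = list(a = tab_a, b = tab_b),
    orthologs = orthologs,
    truth = list(enhancers_a = tab_a, enhancers_b = tab_b, cross = cross,
                 motifs_a = enh_a$motifs),
    config = cfg), class = "ire_simulation")
}

# plant one species' enhancer complement; returns updated genome (list of
# char vectors), the enhancer table, and per-enhancer planted-motif
# offsets
plant_species_enhancers <- function(genome_chars, genes, cfg, prefix,
                                    only_genes = NULL, occupied = list()) {
  gene_pool <- if (is.null(only_genes)) genes$gene_id else only_genes
  n_enh <- if (is.null(only_genes)) cfg$n_enhancers else
    round(cfg$n_enhancers * length(only_genes) / nrow(genes))
  if (length(gene_pool) == 0 || n_enh == 0) {
    return(list(genome = genome_chars,
                table = empty_enhancer_table(), motifs = list()))
  }
  host <- sample(gene_pool, n_enh, replace = TRUE)
  n_ire <- round(cfg$ire_fraction * n_enh)
  class <- c(rep("IRE", n_ire), rep("non-IRE", n_enh - n_ire))
  fc <- ifelse(class == "IRE",
               stats::runif(n_enh, cfg$fc_range[1], cfg$fc_range[2]), 1)
  rows <- list(); motifs <- list()
  # `occupied` accumulates taken spans per chromosome to avoid overlap
  for (i in seq_len(n_enh)) {
    g <- genes[genes$gene_id == host[i], ]
    chrlen <- length(genome_chars[[g$chrom]])
    for (try in 1:100) {
      dist <- sample(2000:(100000 - cfg$enhancer_length), 1)
      side <- sample(c(-1, 1), 1)
      start <- g$tss + side * dist - if (side < 0) cfg$enhancer_length else 0L
      start <- as.integer(start)
      if (start < 0 || start + cfg$enhancer_length > chrlen) next
      span <- c(start, start + cfg$enhancer_length)
      occ <- occupied[[g$chrom]]
      clash <- !is.null(occ) && any(span[1] < occ[, 2] & span[2] > occ[, 1])
      if (!clash) break
    }
    occupied[[g$chrom]] <- rbind(occupied[[g$chrom]], span)
    nm <- sprintf("%s%03d", prefix, i)
    counts <- if (class[i] == "IRE") cfg$motifs_ire else cfg$motifs_nonire
    planted <- plant_enhancer(genome_chars[[g$chrom]], start, cfg,
                              counts[["ap1"]], counts[["ets"]])
    genome_chars[[g$chrom]] <- planted$chars
    motifs[[nm]] <- planted$motifs
    rows[[i]] <- data.frame(chrom = g$chrom, start = start,
                            end = start + cfg$enhancer_length,
                            name = nm, strand = "*", gene_id = host[i],
                            class = class[i], fold_change = fc[i],
                            ap1_planted = sum(planted$motifs$family == "AP-1"),
                            ets_planted = sum(planted$motifs$family == "ETS"),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(genome = genome_chars, table = tab, motifs = motifs)
}

empty_enhancer_table <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), strand = character(0),
             gene_id = character(0), class = character(0),
             fold_change = numeric(0), ap1_planted = integer(0),
             ets_planted = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.ire_simulation <- function(x, ...) {
  cat(sprintf(
    "<ire_simulation> seed %d: %d+%d enhancers (A: %d IREs), %d orthologs\n",
    x$config$seed, nrow(x$enhancers$a), nrow(x$enhancers$b),
    sum(x$enhancers$a$class == "IRE"), nrow(x$orthologs)))
  invisible(x)
}

#' Simulate replicated ChIP region counts
#'
#' Counts per region, replicate and condition are negative binomial with
#' mean `depth` (times the planted fold change for IREs in the injured
#' condition) and the configured dispersion. Library sizes are recorded as
#' a fixed multiple of the column sums.
#'
#' @param sim an [simulate_genome_pair()] result, or `NULL` to simulate
#'   free-standing regions.
#' @param species `"a"` or `"b"` (when `sim` is given).
#' @param config overrides `sim$config` when supplied; required when
#'   `sim` is `NULL`.
#' @param n_regions,fold_changes used when `sim` is `NULL`: number of
#'   regions and their per-region injury fold changes (default all 1).
#' @param seed RNG seed; defaults to the config seed plus a fixed offset.
#' @return A [region_count_table()]; planted fold changes are attached to
#'   the regions as a `fold_change` column.
#' @export
simulate_chip_counts <- function(sim = NULL, species = "a", config = NULL,
                                 n_regions = NULL, fold_changes = NULL,
                                 seed = NULL) {
  cfg <- if (!is.null(config)) config else sim$config
  if (is.null(cfg)) stop("config required")
  if (is.null(seed)) seed <- cfg$seed + 101L
  set.seed(seed)
  if (!is.null(sim)) {
    tab <- sim$enhancers[[species]]
    regions <- tab[, c("chrom", "start", "end", "name", "strand",
                       "gene_id", "fold_change")]
    fc <- tab$fold_change
  } else {
    if (is.null(n_regions)) stop("n_regions required without a simulation")
    if (is.null(fold_changes)) fold_changes <- rep(1, n_regions)
    fc <- fold_changes
    regions <- data.frame(chrom = "sim", start = (seq_len(n_regions) - 1L) * 2000L,
                          end = (seq_len(n_regions) - 1L) * 2000L + 1000L,
                          name = sprintf("region%04d", seq_len(n_regions)),
                          strand = "*", fold_change = fc,
                          stringsAsFactors = FALSE)
  }
  nrep <- cfg$replicates
  n <- nrow(regions)
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
  draw <- function(mu) {
    if (is.finite(size)) stats::rnbinom(n, size = size, mu = mu)
    else stats::rpois(n, mu)
  }
  ctl <- vapply(seq_len(nrep), function(r) draw(rep(cfg$depth, n)),
                numeric(n))
  inj <- vapply(seq_len(nrep), function(r) draw(cfg$depth * fc), numeric(n))
  counts <- cbind(matrix(ctl, nrow = n), matrix(inj, nrow = n))
  colnames(counts) <- c(paste0("control_", seq_len(nrep)),
                        paste0("injured_", seq_len(nrep)))
  rownames(counts) <- regions$name
  # libraries sequenced to (the same) full depth: the counted regions are a
  # small fraction of each library, so planted induction does not shift the
  # library size
  lib <- rep(ceiling(max(colSums(counts)) * 20), ncol(counts))
  region_count_table(regions, counts,
                     condition = rep(c("control", "injured"), each = nrep),
                     replicate = rep(seq_len(nrep), 2),
                     lib_size = lib)
}

#' Simulate bulk RNA counts
#'
#' Gene baselines are log-normal around the configured depth; genes linked
#' to at least one planted IRE are induced by `rna_induced_fc` in the
#' injured condition. Counts are negative binomial with the configured
#' dispersion.
#'
#' @param sim an `ire_simulation`; gene-IRE links come from its truth.
#' @param species `"a"` or `"b"`.
#' @param seed RNG seed (defaults to config seed + 202).
#' @return List: `counts` (genes x samples), `condition`, `lengths`
#'   (transcript lengths for [tpm()]), `truth` (per-gene induction flag).
#' @export
simulate_rna_counts <- function(sim, species = "a", seed = NULL) {
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg$seed + 202L
  set.seed(seed)
  genes <- sim$genes[[species]]
  enh <- sim$enhancers[[species]]
  induced <- genes$gene_id %in% enh$gene_id[enh$class == "IRE"]
  n <- nrow(genes)
  base <- stats::rlnorm(n, meanlog = log(cfg$rna_depth), sdlog = 0.5)
  fc <- ifelse(induced, cfg$rna_induced_fc, 1)
  nrep <- cfg$replicates
  size <- 1 / cfg$dispersion
  ctl <- vapply(seq_len(nrep), function(r)
    stats::rnbinom(n, size = size, mu = base), numeric(n))
  inj <- vapply(seq_len(nrep), function(r)
    stats::rnbinom(n, size = size, mu = base * fc), numeric(n))
  counts <- cbind(ctl, inj)
  colnames(counts) <- c(paste0("control_", seq_len(nrep)),
                        paste0("injured_", seq_len(nrep)))
  rownames(counts) <- genes$gene_id
  list(counts = counts,
       condition = rep(c("control", "injured"), each = nrep),
       lengths = sample(500:3000, n, replace = TRUE),
       truth = data.frame(gene_id = genes$gene_id, induced = induced,
                          fold_change = fc, stringsAsFactors = FALSE))
}

#' Simulate a single-cell RNA count matrix
#'
#' Cells carry a type and a condition; each induced gene has one true cell
#' type in which (and only in which) its mean is multiplied by
#' `sc_induced_fc` under injury. Baseline gene-by-type means are gamma
#' distributed; counts are Poisson per cell.
#'
#' @param config a [sim_config()].
#' @param genes optional gene ids (defaults to `G001...`).
#' @param induced_fraction fraction of genes that are induced (default 1:
#'   the procedure is applied to up-regulated genes).
#' @param seed RNG seed (defaults to config seed + 303).
#' @return List: `counts` (genes x cells), `cell_meta` (`cell_id`, `type`,
#'   `condition`), `truth` (`gene_id`, `true_type`, `induced`).
#' @export
simulate_sc_counts <- function(config, genes = NULL, induced_fraction = 1,
                               seed = NULL) {
  cfg <- config
  if (is.null(seed)) seed <- cfg$seed + 303L
  set.seed(seed)
  types <- CELL_TYPES[seq_len(cfg$sc_types)]
  ng <- cfg$sc_genes
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(ng))
  ncell_per <- cfg$sc_cells_per_type
  meta <- expand.grid(type = types, condition = c("control", "injured"),
                      cell = seq_len(ncell_per), stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = sprintf("cell%05d", seq_len(nrow(meta))),
                     type = meta$type, condition = meta$condition,
                     stringsAsFactors = FALSE)
  base <- matrix(stats::rgamma(ng * length(types), shape = 2, rate = 1) + 0.2,
                 nrow = ng, dimnames = list(genes, types))
  induced <- stats::runif(ng) < induced_fraction
  true_type <- sample(types, ng, replace = TRUE)
  counts <- matrix(0L, nrow = ng, ncol = nrow(meta),
                   dimnames = list(genes, meta$cell_id))
  for (j in seq_len(nrow(meta))) {
    mu <- base[, meta$type[j]]
    if (meta$condition[j] == "injured") {
      boost <- induced & true_type == meta$type[j]
      mu[boost] <- mu[boost] * cfg$sc_induced_fc
    }
    counts[, j] <- stats::rpois(ng, mu)
  }
  list(counts = counts, cell_meta = meta,
       truth = data.frame(gene_id = genes, true_type = true_type,
                          induced = induced, stringsAsFactors = FALSE))
}

#' Write a simulation to disk in standard formats
#'
#' Emits, per species: `genome_<s>.fa`, `genes_<s>.gtf`,
#' `enhancers_<s>.bed`; plus `orthologs.tsv` and `truth_cross.tsv`. Output
#' is byte-identical across runs for a fixed config seed.
#'
#' @param sim an `ire_simulation`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sp in c("a", "b")) {
    fa <- file.path(dir, paste0("genome_", sp, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genomes[[sp]]), fa)
    gtf <- file.path(dir, paste0("genes_", sp, ".gtf"))
    write_gene_models_gtf(sim$genes[[sp]], gtf)
    bed <- file.path(dir, paste0("enhancers_", sp, ".bed"))
    write_bed(sim$enhancers[[sp]], bed)
    paths <- c(paths, fa, gtf, bed)
  }
  orth <- file.path(dir, "orthologs.tsv")
  write_ortholog_table(sim$orthologs, orth)
  cross <- file.path(dir, "truth_cross.tsv")
  utils::write.table(sim$truth$cross, cross, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, orth, cross))
}
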