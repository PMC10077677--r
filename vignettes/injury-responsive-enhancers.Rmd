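---
title: "Identifying and comparing injury-responsive enhancers across species"
author: "irekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and comparing injury-responsive enhancers across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irekit)
```

# Scope and model

Injury-responsive enhancers (IREs) are distal cis-regulatory elements whose
active-enhancer mark (H3K27ac) rises significantly after tissue injury.
`irekit` implements the comparative workflow around that definition: calling
IREs from replicated region counts, characterizing their AP-1/ETS motif
content, mapping each IRE onto orthologous sequence in a second species,
and deciding whether the orthologous sequence is itself injury-responsive
(shared) or not (species-specific). Every stage can be exercised end to end
on synthetic two-species data in which the truth is planted, so the
operating characteristics reported by the test suite are measured, not
assumed.

All intervals are 0-based half-open (BED convention); GTF input is
converted on read. One TSS is kept per gene (isoform-aware TSS selection is
out of scope).

# Differential enhancer calling

The input is a `region_count_table`: peak regions by samples, with a
condition label (injured/control), replicate ids and library sizes. The
statistical model is deliberately compact and fully stated:

* Counts are adjusted to a common library size (`lib_size / mean(lib_size)`).
* A single negative-binomial dispersion `phi` is estimated across all
  regions by the method of moments: within each (region, condition) cell
  with replicates, the sample variance of adjusted counts is matched to
  `mu/s + phi * mu^2` and the per-region estimates are pooled with `mu^2`
  weights. Zero or one replicate per condition degenerates to the Poisson
  limit (with a warning).
* Per region, the per-group sums of adjusted counts are compared through
  the conditional distribution of one group's sum given the total, each
  group sum being NB with size `n_g / phi`. The two-sided p-value sums the
  probabilities of all splits no more probable than the observed one; for
  totals above 50,000 a normal approximation takes over. `phi = 0` gives
  the exact binomial (Poisson) conditional test.
* FDR by Benjamini–Hochberg.

A region is called **IRE** when its pseudocounted fold change
`(m_inj + 0.5)/(m_ctl + 0.5)` reaches 1.5 *and* the chosen criterion
metric (FDR, default threshold 0.05; or the raw p-value, threshold 0.01
for the variant rule) is below the threshold. Regions not called but with
mean normalized signal of at least 1 count per million in *both*
conditions are **non-IRE** (active, no increase); everything else is
**excluded**. `define_ires()` then applies the distal rule: up-called
peaks whose midpoint lies within ±2 kb of any TSS are excluded as
promoter-proximal. The pseudocount of 0.5 guards zero counts; the
1 cpm activity floor operationalizes "active in both conditions", which
the rest of the workflow treats as a configuration value.

On planted truth (200 four-fold regions among 1,000 nulls, dispersion
0.1, 2+2 replicates) the caller reaches sensitivity ≥ 0.9 at an empirical
FDR under 0.05, and on null data the p-values are calibrated (fraction
below 0.05 within binomial error of 0.05). These numbers are recomputed by
`scripts/acceptance.R` on every run.

A power remark worth making explicit: with dispersion `phi` and `n`
replicates per group, the variance of the log fold-change estimate is
bounded below by `phi * 2/n` regardless of sequencing depth. At
`phi = 0.1` and 2+2 replicates a 3-fold change yields at most
`z ≈ ln(3)/sqrt(0.1) ≈ 3.5`, so no test can push sensitivity for 3-fold
changes much past ~0.75 at usual FDR levels; 4-fold changes
(`z ≈ 4.4`) are comfortably recoverable. The defaults of the synthetic
generator (fold changes 3–6) sit across this transition on purpose.

# Motif scanning and frequency

Motifs are IUPAC degenerate codes; the built-in registry holds the two
family consensus codes — AP-1 `TKASTMA`, ETS `VVGGAWVY` — and 21
per-factor codes (14 ETS, 7 AP-1). Scanning tests *every* sliding-window
offset, so overlapping matches are counted. Lowercase (soft-masked) bases
are uppercased first. An `N` in the subject matches only an `N` pattern
position; pattern `N` matches any base. Three strand modes are provided:
`forward`, `both_dedup` (unique forward-coordinate windows matched on
either strand — the default) and `both_sum`. Because `TKASTMA` is its own
IUPAC reverse complement, the AP-1 count is strand-mode invariant; ETS
counts can differ roughly two-fold between `both_dedup` and `both_sum`,
which is why the mode is an explicit flag rather than a constant.

Motif frequency is `f = 1000 * c / s` per kilobase over each region's full
native length. The scanner is verified against a brute-force oracle that
expands each degenerate code into its complete concrete word set and
string-searches every word.

Enrichment is a deliberately simple presence/absence Fisher exact test
against a GC-matched background (regions binned by GC fraction at a 0.02
tolerance, sampled without replacement to reproduce the target histogram).
It is a stand-in for log-odds motif-model enrichment, suitable for
planted-truth validation, and is not expected to reproduce any specific
motif-discovery tool's p-values. The relative overlapping ratio
`r_i = n_i / n_0` bins (typically random 1-kb) sequences by motif
frequency and asks how often each bin overlaps TF peaks, with a
length/chromosome-preserving peak shuffle as its negative control.

# Signal matrices, enhancer states, conservation

`signal_matrix()` bins coverage in ±flank windows around region midpoints
or TSSs (minus-strand windows flipped), verified against a per-base loop.
`classify_enhancer_states()` runs k-means with k = 3 on the concatenated
H3K27ac/H3K27me3 rows and names clusters by a fixed rule: highest mean
H3K27me3 is *poised*; of the rest, higher mean H3K27ac is *active*, the
other *primed*. R's Hartigan–Wong k-means with 10 random restarts under a
fixed seed is used (no k-means++ initializer in base R; with 10 restarts
the three-population recovery tested is exact). Conservation scores are
averaged over 1-kb windows centered on region midpoints; uncovered bases
are excluded from the mean and a fully uncovered window is `NA`, never
zero.

# Expression and cell-type assignment

TPM follows the standard length-then-depth normalization and sums to 10⁶
per sample by construction. The simplified differential-expression test
reuses the NB machinery with median-of-ratios size factors (robust to a
minority of strongly induced genes). The scRNA procedure scales each cell
to 10,000 counts, applies `log1p`, computes per-gene per-type fold changes
of mean normalized expression (injured vs uninjured, pseudocount 0.01 on
both means to guard zero baselines), and assigns each gene to the argmax
type; exact ties break by the fixed type order, and "largest change" means
largest positive fold change (the procedure is applied to up-regulated
genes; an absolute-value flag is provided).

# Orthologous enhancer mapping

Ortholog resolution keeps, per query gene, the candidate with the highest
percent identity (ties to the lexicographically smaller target id). The
aligner is an affine-gap Gotoh DP with match +5, mismatch −4 and gap cost
`10 + 0.5·L` — a gap of length L pays the opening penalty once plus a
per-base extension. In `global_align()` end gaps are penalized, which the
`("A", "")` score of −10.5 pins down; `N` scores as a mismatch against
everything; traceback ties resolve diagonal > up > left so output is
deterministic.

Mapping an IRE into the other species aligns its sequence against the
±100 kb window around the orthologous gene's TSS in **glocal** mode: the
query aligns end to end, the window's flanks are free. This matters
because a strictly global alignment of ~1 kb against 200 kb would consist
almost entirely of end gaps and its column-wise identity would be
meaningless; identity here is computed over the aligned core. The mapped
interval is the minimal target span covering all aligned (non-gap)
columns. A mapping is declared **unmapped** below 50% core identity: for a
1-kb query, unrelated windows reach 39 ± 2% identity by chance (the glocal
DP picks the best-looking subregion), so the floor sits several standard
deviations above the null while genuine homologs retain ~80% identity even
at 20% divergence.

For windows whose DP size exceeds 4×10⁷ cells the quadratic DP is first
localized by seed matching — exact query 12-mers vote for their diagonal,
and the exact DP runs on the winning subwindow with a query-length margin;
if no diagonal collects at least 5 votes the full exact DP runs anyway.
On every planted benchmark the seeded path returns byte-identical results
to the full DP at a fraction of the cost. Below the cell threshold
(roughly windows under 20 kb for a 1–2 kb query) the exact DP is used
unconditionally, which keeps oracle tests exact.

Classification: an IRE whose mapped interval overlaps an IRE of the other
species by ≥ 1 bp (configurable) is *shared*; mapped without overlap is
*species-specific*; no accepted mapping is *unmapped*. Gene-level classes
(common / species-specific / no-ortholog) resolve through the ortholog
map.

# Assay arithmetic

Luciferase activation is the double ratio
`FC = (s_i(H)/s_i(N)) / (s_c(H)/s_c(N))` on Renilla-normalized means;
per-replicate fold changes, their SEM, and a Welch t-test against the
empty-vector replicates are also reported (an equal-variance flag is
provided, since the choice is not determined by the double-ratio formula
itself). ΔΔCT relative expression is `2^(−ΔΔCT)` with the reference gene
subtracted per measurement and the baseline condition's mean ΔCT as the
anchor. Both are invariant to the nuisance factors they are designed to
cancel (per-replicate transfection efficiency; constant CT shifts), and
the tests assert exactly that.

# The synthetic generator: what it does and does not emulate

`simulate_genome_pair()` builds two genomes of i.i.d. bases at a
configured GC (default 0.42), places genes with regular spacing, plants
enhancers 2–100 kb from their host TSS (1 kb long by default,
non-overlapping), and writes class-controlled motif content into them:
IREs get 1 AP-1 + 3 ETS planted consensus realizations by default,
non-IREs 0 + 1. A configurable fraction of species-A genes has a species-B
ortholog; each enhancer of an orthologous gene is copied near the B
ortholog's TSS at a per-base substitution divergence `d` (substitutions
always change the base, so realized divergence matches `d` up to binomial
noise). A copied IRE either stays injury-responsive in B (*shared*) or,
with the ablation probability, has each planted motif scrambled until no
family-consensus match overlaps its span — modelling the empirical
association between motif-frequency loss and loss of inducibility, without
claiming a mechanism. Species B additionally gets its own enhancers at
non-orthologous genes. ChIP counts are NB around a per-region depth
(default 100) times the planted fold change under injury; library sizes
are equal across samples, as for libraries sequenced to the same depth
(the counted regions are a small fraction of a real library, so planted
induction must not shift the size factors). RNA counts induce IRE-linked
genes; the scRNA matrix gives each induced gene one true cell type whose
injured cells carry the induction.

What the generator does **not** emulate — and therefore what passing
tests do *not* demonstrate about real data: repeat structure and
mappability artifacts, GC bias, fragment-level read placement, peak-calling
uncertainty (candidate peaks are inputs throughout), indel divergence
between orthologs (substitutions only), doublets or ambient RNA in the
scRNA matrix, and any correlation structure between neighbouring regions.
Results on real data additionally depend on the upstream aligner, peak
caller and annotation quality, all of which are outside this package's
scope.

All generator outputs are byte-identical under a fixed seed (verified by
checksum in the tests). Default scales — 2 chromosomes × 2 Mb per species,
200 genes, 300 enhancers — generate in well under a minute; the test and
acceptance runs use a single 600 kb chromosome with 30 genes and 24
enhancers for the cross-species stages, which preserves every planted
property at a fraction of the alignment cost.

# Numerical choices and degenerate inputs

* Fold-change pseudocount 0.5 (region counts), scRNA pseudocount 0.01.
* Exact-test enumeration capped at totals of 50,000; normal approximation
  beyond.
* Empty libraries, one-condition designs, zero-length windows, all-missing
  conservation windows, promoterless gene sets and empty annotation sets
  all raise errors or return flagged values (`NA`, `unmapped`) rather than
  silent zeros.
* Tie-breaks are deterministic and documented: nearest-gene ties by
  smaller TSS then gene id; ortholog ties lexicographic; cell-type ties by
  the fixed type order; alignment traceback diagonal > up > left.
* `gc_matched_background` errors when a GC bin cannot be filled, naming
  the bin, instead of silently relaxing the match.

# Known limitations

The NB exact-style test rounds library-size-adjusted counts before
conditioning, which is standard but slightly conservative for very shallow
libraries. The common-dispersion assumption pools information across
regions and will under-serve datasets with strongly region-dependent
dispersion. The motif enrichment stand-in tests presence only, not match
counts or affinities. Glocal identity is computed over the aligned core,
so reported identities are not comparable to global-alignment identities
of equal-length sequences. The luciferase t-test is a plain two-sample
test on replicate ratios and will return `NA` on degenerate
(zero-variance) replicate sets.
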