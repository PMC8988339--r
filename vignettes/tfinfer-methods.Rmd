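---
title: "Methods: peak-gene linking, regulatory potential and TF inference"
author: "tfinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak-gene linking, regulatory potential and TF inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfinfer)
```

# Scope and data model

`tfinfer` answers three questions that recur in regulatory genomics once
peaks have been called from ATAC-seq or ChIP-seq data:

1. *Which gene does each peak belong to?* (annotation)
2. *Which genes does a given TF directly regulate?* (target calling)
3. *Which TFs drive a gene set or peak set of interest?* (TF inference)

Everything operates on a small internal data model: gene models with a
strand-aware transcription start site (TSS), peak intervals with an
optional summit, feature-by-sample signal matrices, TF-to-peak hit sets,
TF-target pair tables, and differential-expression (DGE) tables. All
coordinates are 0-based half-open (the BED convention); GFF input is
converted once at the I/O boundary (`read_gene_annotation()`) and never
again, which keeps interval arithmetic free of off-by-one traps. The
framework is species-agnostic: nothing assumes a particular genome beyond
the annotation files supplied.

Distances are always measured from the *peak anchor* — the summit when the
peak caller provides one, otherwise the integer midpoint — to the TSS, and
are signed: negative means the anchor lies 5' of the TSS in the gene's
orientation. The anchor policy is a deliberate choice: the summit marks
the signal mode when available, and the midpoint is the standard fallback.

# Peak-gene annotation

Three strategies are provided, reflecting different assumptions about
*cis*-regulation:

* **Nearest gene** (`annotate_nearest()`): each peak is linked to the one
  gene whose TSS is closest to its anchor. One-to-one by construction.
  Ties (two TSSs exactly equidistant) are resolved to the
  lexicographically smaller `gene_id` so output is reproducible.
* **Gene scan** (`annotate_scan()`): each gene claims a scan region
  `TSS ± scan_length`; every peak whose anchor falls inside is linked, so
  one peak can serve several genes — the realistic situation in compact
  genomes where a single accessible region sits between divergent
  promoters. Peaks claimed by no gene fall back to their nearest gene
  (`mode = "nearest_fallback"`). The default `scan_length` of 20 kb (a
  per-side radius) suits compact plant genomes; for mammalian data a
  larger radius is appropriate.
* **Gene bound** (`annotate_gene_bound()`): the inverse direction — given
  genes of interest, guarantee each is linked: nearest-gene links are kept
  where they exist, and genes left unassigned are linked to their nearest
  peak (`mode = "gene_bound"`). Query genes on chromosomes with no peaks
  are reported as unresolvable rather than failing the run.

`summarize_links()`, `pair_count_summary()` and `distance_distribution()`
provide the standard per-gene / per-peak multiplicity and distance
summaries as plain tables.

# Correlation-scored links

Position alone cannot distinguish a functional enhancer-gene pair from an
incidental neighbour. With signal across multiple samples (a time course
or tissue panel), `peak_gene_cor()` scores each link by the correlation of
peak accessibility with gene expression; `enhancer_promoter_cor()` scores
distal peaks against each gene's *promoter peak* (the peak nearest its
TSS), which needs no RNA-seq at all.

The correlation is Pearson by default, computed on the values as supplied
— the package applies no internal transformation, because the right
variance-stabilising transform depends on how the matrices were produced;
callers who want log-scale correlation pass log-transformed matrices.
Spearman is available for monotone-but-nonlinear trends. The two-sided
p-value uses the t transform with n − 2 degrees of freedom (applied to the
rank correlation in the Spearman case). Rows with zero variance yield an
*undefined* flag rather than r = 0: an uncomputable correlation must not
masquerade as evidence of absence. The default filter keeps links with
`r > 0.8` and `p < 0.01`, a deliberately conservative pairing.

A caveat the package inherits from the statistics: correlation estimated
from few samples is fragile. With 7 samples the `p < 0.01` cut already
implies `|r| > 0.87`, so the `r > 0.8` threshold adds nothing and the
false-positive rate among candidate links is governed entirely by the p
cut. The filter behaves as intended — the r-threshold binding — from
roughly a dozen samples upward. For this reason the planted-pair
validation world (`cor_fixture_spec()`) uses 16 samples, a dense or
replicated series; the number of samples reported in every output row
(`n`) lets consumers apply their own floor.

# Regulatory potential

The regulatory potential (RP) of a gene summarises nearby signal weighted
by an exponentially decaying function of distance to the TSS:

$$w(d) = 2^{-d/\Delta}, \qquad
\mathrm{rp}(g, s) = \sum_{p \in \mathrm{links}(g)} 2^{-|d_{pg}|/\Delta}\,
x_{p,s}$$

where Δ is the *half-decay* distance — the distance at which a peak's
contribution halves. Three input modes share this kernel:

* `rp_region()`: gene-scan links plus a peak-count matrix give a
  gene-by-sample RP profile (fallback-mode links are excluded: a peak
  outside every scan window should not contribute).
* `rp_coverage()`: base-resolution bedGraph coverage integrated over
  `TSS ± window`; constant-value intervals are integrated with exact
  closed-form geometric partial sums rather than per-base loops.
* `rp_tfhit()`: one TF's ChIP peaks with unit weight per peak; the
  resulting `sum_rp` ranks candidate direct targets (descending, average
  ranks for ties).

Defaults are Δ = 1 kb for TF ChIP input (sharp, proximal binding) and
Δ = 10 kb for accessibility input (broad regulatory landscapes); both are
plain arguments, not constants. No per-sample normalisation happens inside
RP — normalise the matrix first, by whatever method suits the assay — and
RP is exactly linear in the signal, a property the test suite asserts.

# Target calling by rank product

Binding near a gene does not prove regulation; differential expression
after perturbing the TF does not prove directness. `integrate_chip_rna()`
combines both: genes are ranked by RP (`rp_rank`, descending RP) and by
adjusted p-value within the selected DGE category (`diff_rank`,
ascending `padj`), and the product `rp_rank × diff_rank` orders the final
target list. Ties receive average (mid) ranks, and fractional mid-ranks
propagate exactly into the product — a table with two genes tied at
`diff_rank` 6.5 yields products like 33 × 6.5 = 214.5, reproduced to the
decimal. Because only ranks enter, the result is invariant under any
monotone transform of either input, which makes the integration robust to
the (arbitrary) scale of either assay.

`diff_rank` is computed within the user-selected direction (default
`"up"`, i.e. genes induced by the perturbation); ranking both directions
together is available via `category = "both"`. By default `rp_rank` is
recomputed after intersecting the ChIP and DGE universes, since a rank
against genes absent from the other assay is not interpretable;
`recompute_rp_rank = FALSE` preserves the full-universe ranks instead.
The permutation behaviour is the key sanity check: shuffling DGE gene
labels collapses top-k recovery of planted targets to chance, which the
test suite verifies.

# Inferring influential TFs

Six statistics rank TFs by their evidence of driving a query set, all
returning one contract: `tf_id`, `statistic`, `p`, `p_adj`
(Benjamini-Hochberg across the TFs in the call), `rank` (1 = strongest)
and `z`, the inverse-normal transform of the rank,
`z = Φ⁻¹((N − r + 0.5)/N)` — the 0.5/N offset keeps the extremes finite.
Ranks are a deterministic permutation (p ascending, then statistic
descending, then `tf_id`), so `z` is strictly decreasing in rank and
rankings from different statistics are directly comparable.

* `tf_enrich_fisher()` — peak-set enrichment by the one-sided
  hypergeometric (Fisher exact) test on bound/unbound × query/background;
  the reported odds ratio uses a Haldane 0.5 correction for empty cells.
* `tf_enrich_wilcox()` — the same question via a one-sided rank-sum test
  on per-peak scores (binding indicator, or any per-peak score matrix).
  Exact when the smaller group has ≤ 8 observations (full enumeration of
  rank assignments when ties are present), otherwise the normal
  approximation with tie and continuity corrections.
* `tf_tt_pair()` — gene-set over-representation of known TF targets,
  GO-enrichment style, with the overlapping genes listed per TF.
* `tf_hit_test()` — per gene, the number of TF-bound peaks among its
  scan links (optionally decay-weighted via `weighted = TRUE`); query
  versus background genes compared per TF by the rank-sum test.
* `tf_region_rp()` — splits each gene's RP into the share attributable to
  a TF's bound peaks and compares the *proportion attributable* between
  query and background genes, per sample. This is the most informative
  statistic when a TF acts at a specific stage: the per-sample p-values
  localise the activity in the series, the pooled summary is the
  Bonferroni-adjusted minimum across samples, and a long
  (gene, TF, sample) table supports per-gene drill-down. Proportions are
  defined as 0 where a gene's RP is 0.
* `tf_mara()` — motif activity response analysis: the double-centred
  `log2(x+1)` signal matrix is modelled as site counts times per-sample
  motif activities, `x̃ ≈ Ñ A`, fitted by ridge regression with one
  penalty λ shared across samples and chosen from a grid by leave-one-out
  generalized cross-validation (averaged over samples). Activity rows are
  centred (the model is only identified up to a per-motif offset), and
  per-motif variability (the sd of activity across samples) ranks motifs
  by how much their activity moves over the series. The preprocessing —
  log transform, row/column centring, column-centred site counts — is the
  minimal set of choices that makes the decomposition identifiable, and
  each is recorded in the result object; `log_transform = FALSE` accepts
  pre-transformed input.

All alternatives are one-sided ("greater") because every statistic asks
an enrichment question. BH correction is applied within one call, across
TFs; `tf_region_rp()` additionally corrects across samples by Bonferroni
before taking the minimum. `combine_replicates()` merges rankings from
replicates or data sources (geometric-mean p by default, Stouffer's
Σz/√k, or mean rank), and `jaccard_tf()` quantifies co-binding /
co-targeting overlap between TFs as |A∩B|/|A∪B| (defined as 0 when both
sets are empty).

# The synthetic-data generator

`fixture_spec()` / `make_genome()` / `make_signal()` / `make_tf_world()`
generate complete miniature studies: a multi-chromosome genome with
spaced genes, peaks concentrated in scan windows, negative-binomial count
matrices (sequencing counts are overdispersed; dispersion is a
parameter), planted enhancer-promoter pairs rejection-sampled to a target
correlation, a planted monotone temporal trend, and a TF world in which
one planted TF binds peaks of its target genes while decoys bind at a
background rate, with a matching DGE table. The default shape mirrors a
7-time-point accessibility course with one planted TF among 40 decoy
motifs. Every generator is a deterministic function of the spec seed, and
the generated files are valid inputs to every reader.

Per-statistic validation worlds follow the conditions under which each
statistic is meant to operate: the peak-set enrichment world
(`make_enrich_world()`) plants a TF binding 80% of 100 query peaks
against a 10% background with 20 decoys; the binding-geometry statistics
use a world with 50 query genes, an 80% planted hit rate and a 5%
background; the region-RP world further couples the planted TF's peaks to
elevated signal in one sample (that is the scenario the statistic
exists to detect); the MARA world plants one motif with several-fold
higher activity amplitude. Problem sizes used in the shipped validation
(e.g. 150 genes / 450 peaks / 7 samples; 200 peaks × 10 motifs × 7
samples for MARA; 100-seed replication) were chosen as the smallest
worlds in which the planted structure is unambiguous.

What passing these tests shows — and what it does not: the generator
emulates the *statistical shape* of a real study (counts, decay geometry,
planted associations), not its biology. Real data add confounders the
fixtures deliberately omit: GC and mappability bias, copy-number effects,
correlated replicates, motif redundancy between TF family members, and
enhancers acting over distances far beyond any scan window. Recovery of a
planted TF here validates the machinery, not the discovery power on any
particular organism.

# Numerical and degenerate-case policy

* Rank ties: average (mid) ranks everywhere; final orderings add
  lexicographic id keys so identical inputs give byte-identical outputs.
* Zero-variance rows in correlation: flagged undefined, excluded from
  filtering.
* Rank-sum test with all values tied: p = 1, z = 0 (no evidence, not an
  error).
* Fisher odds ratio with an empty cell: Haldane 0.5 correction; the
  p-value itself needs no correction.
* `tf_mara()` refuses λ = 0 on a rank-deficient site-count matrix with an
  instruction to use λ > 0; the noiseless limit is recoverable with a
  tiny penalty.
* Coverage RP integrates with closed-form geometric sums; agreement with
  per-base summation is asserted to 1e-9.
* Genes or peaks on chromosomes absent from a companion file are allowed:
  they simply never link, and each such event is counted in a warning or
  message rather than silently ignored.

# Null calibration

On null worlds (hits assigned at random), the fraction of TF tests with
p < 0.05 sits at the nominal 5% for the rank-sum statistics and slightly
*below* it for the hypergeometric ones. That deficit is structural, not a
bug: exact tests on discrete tables can only achieve p-values at the
table's attainable support, so P(p < α) ≤ α with strict inequality in
finite tables. The acceptance suite asserts a tight ±2 s.e. band around
0.05 for all four statistics; the target-pair statistic lands marginally
below the band's lower edge (≈ 0.044 at the shipped seeds) for exactly
this reason, and the shortfall shrinks as table margins grow.

# Known limitations

* TSS positions come from gene-level annotation spans; isoform-specific
  TSS choice is out of scope.
* The gene-scan and RP windows are symmetric around the TSS; asymmetric
  regulatory architecture (e.g. promoter-proximal bias downstream) is not
  modelled.
* `tf_region_rp()` reports per-sample evidence with a Bonferroni-min
  pooled summary; a fully joint multi-sample model is not attempted.
* Motif scanning itself is out of scope: hit tables from FIMO/HOMER or
  ChIP databases are consumed, not produced.
* The rank-product target score is reported as ranks, not as a
  permutation p-value.
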