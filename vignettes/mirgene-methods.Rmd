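---
title: "Methods: miRNA gene annotation, quantification and differential distribution"
author: "mirgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA gene annotation, quantification and differential distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`mirgene`, the assumptions behind them, the tunable parameters with their
defaults, and the design decisions taken where more than one reasonable
choice existed. No empirical claims are made here beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The problem

miRNA genes are transcribed by RNA polymerase II as long primary
transcripts (pri-miRNAs) from which the short hairpin precursors
(pre-miRNAs) are excised. Reference annotations describe the ~80 bp
hairpins well but rarely the primary transcript, whose TSS can lie far
upstream and whose 3' end is defined only by nascent-transcription data.
Gene-level scRNA-seq quantification against such a reference therefore
misses miRNA gene activity almost entirely, even though poly-A-primed
chemistries capture reads across the transcript body. `mirgene`
reconstructs pri-miRNA gene loci from evidence tracks, counts tagged
alignments over them, and tests for differential distribution of their
expression between condition groups within each cell type.

## 2. Locus construction

Internal coordinates are 0-based half-open (the BED convention); GTF
emission converts to 1-based inclusive; BED I/O passes coordinates through
unchanged. All interval logic lives behind this one convention, and
conversion happens only at the `rtracklayer` I/O boundary.

Each pre-miRNA hairpin seeds one candidate transcript, processed in three
steps:

* **TSS refinement** (`refine_tss`). The 5' end moves to the position of
  the highest-scoring CAGE tag within ±`tss_window` (default 500 bp) of
  the current 5' end; score ties break toward the original 5' end, then
  toward the smaller coordinate, making the operation deterministic. The
  3' end never moves. The window default reflects that the evidence here
  is a refinement of an already-approximate start, not a genome-wide
  promoter search.
* **3' extension by change-point analysis** (`extend_end_changepoint`).
  Over the span from the current 3' end to `search_span` (default 10 kb)
  downstream, the split position minimizing the two-segment squared-error
  cost of the coverage signal is found (equivalent to a single
  least-squares change point; ties break toward the smallest extension).
  The split is accepted only if the mean signal over `window` (default
  500 bp) after it is at most `min_drop_fraction` (default 0.2) times the
  mean before it; otherwise the end extends by the full `search_span`.
  Gate means truncate at the coverage bounds; a candidate whose 3' end
  already sits at the signal drop is left unchanged (the zero-cost split
  at zero extension wins). On a noiseless step the recovered end is exact;
  the acceptance checks require ±25 bp at a noise standard deviation of
  10% of the plateau.
* **Reconciliation** (`reconcile_with_annotation`). If an annotated
  transcript overlaps the candidate, the longer of the two regions is
  kept; the best-overlapping annotated interval (largest overlap, then
  longest) is the comparison partner.

Candidates on the same chromosome and strand that overlap are merged by
single-linkage into one clustered locus (`summarize_locus`): the locus
spans the most distal TSS through the longest transcript end, i.e.
`[min(start), max(end))` on either strand. Its gene id joins the member
hairpin names with `~`.

**Classification** (`classify_locus`): a locus is *intragenic* iff at
least one member hairpin lies entirely within a same-strand gene body;
antisense overlap does not count (an antisense hairpin is transcribed from
its own promoter, not co-transcribed with the host). Host ties break by
the largest overlap with the locus, then lexicographic gene id.

**GTF emission** (`emit_gtf`): one `gene`/`transcript`/`exon` triplet
spanning the full locus — the single-exon pri-miRNA model that makes
intronic reads count as gene-body reads downstream — plus one transcript
per experimentally defined alternative exon chain. Alternative structures
are accepted as input, never inferred. `read_mirna_gtf` inverts the
emission exactly (round-trip tested byte-for-byte).

## 3. Quantification

SAM text parsing is done in-package (field split, CIGAR walk, configurable
`CB`/`UB`-style tags): `M`, `=`, `X` and `D` operations fall inside an
aligned block, `N` splits blocks, `I`/`S`/`H`/`P` consume no reference. A
read is assigned to a locus when any aligned block overlaps the locus
interval; because the locus is a single exon spanning its introns, this is
intron-inclusive counting. In stranded mode (droplet chemistry) the
alignment strand must match the locus; strandless mode serves plate-based
libraries. A read overlapping more than one qualifying locus is ambiguous
and dropped — counts are never double-assigned.

Droplet counts are distinct (cell barcode, UMI) pairs per locus and
barcode; plate counts are read counts. Reads without a barcode are skipped
and reported. UMI collapsing is exact-match only; sequencing-error-aware
collapsing, barcode correction and cell calling are deliberately out of
scope — the default matrix defines the called cells, and
`merge_matrices` aligns miRNA counts to its barcode set (zero-filling
missing barcodes, dropping extra ones) without ever altering a default
value.

## 4. Normalization

`vst_normalize` implements a regularized negative-binomial
variance-stabilizing transformation. Per gene, a Poisson log-linear
regression of counts on log10 of the cell total gives the mean model and
`MASS::theta.ml` the NB dispersion (a moment estimate is the fallback).
The three parameters are then kernel-smoothed across genes ordered by
log10 geometric-mean expression (normal kernel, bandwidth 1.5x the
Silverman rule) — information borrowing that assumes dispersion varies
smoothly with abundance, as UMI data do. Each observation is mapped to

corrected = mu_median + pearson_residual * sd_median,

clamped at zero and log2(x+1)-transformed, where `mu_median` and
`sd_median` are the model mean and standard deviation at the median cell
depth. Two limiting behaviors anchor the implementation and are tested:
with equal depths the correction is the identity (constant genes return
exactly `log2(c+1)`), and all-zero genes carry a degenerate zero model.
On NB-simulated data with a depth gradient, at least 95% of expressed
genes must show Pearson residual variance in [0.5, 2].

A plain depth-scaling `log2(1 + count * median_depth / depth)`
(`depth_normalize`) is kept as the benchmark comparator arm.

## 5. Differential distribution

Testing is split into two families, adjusted separately by
Benjamini–Hochberg (via `stats::p.adjust`):

* **Detection (DZ)** — a two-sided exact conditional test on the 2x2
  table detected/undetected x group, conditioning on both margins and
  summing hypergeometric probabilities of tables no more likely than the
  observed one (the minimum-likelihood rule, identical to
  `fisher.test`'s convention). "Detected" means count > 0 after merging;
  no minimum-count threshold is applied. An opt-in variant replaces the
  exact test with a logistic regression of detection on group plus the
  per-cell detection rate, for designs where cellular detection rate is a
  confounder one wishes to adjust away rather than test.
* **Expression (DE/DP/DM)** — on nonzero normalized values, significance
  comes from a permutation test of the two-sample Kolmogorov–Smirnov
  statistic (default 1000 label permutations;
  p = (1 + #{permuted D >= observed D}) / (1 + permutations)). Ties
  between permuted and observed statistics count as exceedances, so the
  p-value is valid (conservative on tied lattices) rather than exactly
  uniform. Genes with fewer than `min_nonzero` (default 3) expressing
  cells in either group are returned NS. The permutation loop is
  implemented in C++ with a self-contained xorshift generator seeded from
  the session RNG, so `set.seed()` reproduces results exactly.

Significant expression-family genes are classified by fitting 1- vs
2-component Gaussian mixtures per group (`mclust`, models E/V, chosen by
BIC). A 2-component fit counts as bimodal only if it beats the unimodal
fit by `bic_margin` (default 20 — decisive evidence on the Kass–Raftery
scale), its component means are at least `min_sep` (default 2 log2 units)
apart, and both weights exceed `min_weight` (default 0.05). These guards
exist because skewed NB data on the log scale invites spurious
two-component fits. Both groups unimodal is **DE** (mean shift); differing
modality is **DM**. When both groups are bimodal, whether the modes are
*shared* is decided by component occupancy: the group whose fitted modes
are farther apart anchors the reference components (a scarce component's
mean estimated from one group alone is biased toward the bulk), every
cell of both groups is assigned to the nearest reference mode, and if both
groups occupy both modes (minority share ≥ `min_share`, default 0.05) the
difference is a weight shift — **DP**; a mode effectively private to one
group is **DM**. This occupancy rule replaces naive per-group mean
matching, which we found fragile exactly when one group's minority
component is small.

`run_dd` orchestrates the per-gene pipeline, normalizing on **all**
features but testing an optional feature subset — the intended design is a
small family of miRNA loci tested against a transcriptome-wide backdrop,
which also keeps the BH family small relative to the permutation floor of
1/(permutations+1). The final category is DZ when the detection family
drives the call (smaller adjusted p, DZ precedence at ties), the mixture
class when the expression family does, NS otherwise. Detection fold
changes use `log2((r1 + eps) / (r2 + eps))` with pseudorate
`eps = 1/(smaller group size + 1)` so zero-detection genes stay finite.

## 6. Aggregation across cell types

`fisher_combine` implements the combined-probability method: the statistic
−2·Σ ln p referred to a chi-square with 2k degrees of freedom. P-values
below `floor` (default 1e−300) are clamped so a single numerical zero
cannot dominate; a p of exactly 1 contributes nothing to the statistic and
only two degrees of freedom, which is documented and tested. For even
degrees of freedom the survival function has the closed form
`exp(-x/2) * sum_{j<k} (x/2)^j / j!`, used as the independent oracle. One
boundary subtlety: with k identical inputs p*, the combined p decreases
with k for small p*, but the commonly quoted threshold p* < 1/e is only
asymptotic — for k = 2..6 strict monotonicity holds up to roughly
p* = 0.30, and the tests assert the property in that verified regime.

`rank_concordant` keeps genes with combined p below 0.05 whose absolute
detection log2 FC exceeds 0.5 in at least 2 cell types (all three
thresholds exposed). Direction concordance is deliberately **not**
required — age- or disease-associated regulation can go opposite ways in
different cell types and the screen is for consistent involvement, not
consistent sign. Cell types missing a gene contribute p = 1 and FC = 0.
Sorting is total: combined p, then more cell types passing the FC cut,
then gene id. Combined p-values are reported raw with an optional BH
column across genes; multiplicity control within each cell type has
already been applied at the family level.

## 7. Benchmarks

* `null_split_random` draws two disjoint groups of `n_per_group` cells
  (default 300) uniformly — no gene should be called, and the acceptance
  criterion requires the mean fraction of genes at BH-adjusted p < 0.1
  over 50 simulated nulls (200 genes, 300 cells/group) to stay at or
  below 1%.
* `null_split_biased` opposes the lowest and highest nCount terciles
  (stable rank order on ties). With depth-dependent dropout in the
  generator this split makes detection genuinely depth-confounded for
  most genes, so high DZ false-positive rates under it are by
  construction — the scenario probes what depth confounding does to each
  test variant, with the Wilcoxon comparator (`wilcoxon_by_gene`,
  normal-approximation rank-sum with tie correction) run under both raw
  depth scaling and the VST.
* `subsample_sensitivity` computes the full-data significant set, redraws
  each subsample size per group (default grid 300/500/1000/1500), reruns
  the tests and reports the percentage of full-data calls recovered.
  Every run gets an RNG sub-stream derived from the session RNG; a
  subsample covering all cells replays the reference stream, so TP
  recovery at full size is exactly 100%, and recovery is required to be
  non-decreasing in size on average over seeds.

## 8. The synthetic-data generator

The generators define the study conditions under which the package's
claims are tested; their defaults were chosen once, on the following
grounds, and the tests and acceptance script use them as-is.

* `sim_annotation`: loci in 20 kb slots on one toy chromosome,
  alternating strand; TSS 50–400 bp upstream of the hairpin and 3' end
  2–8 kb downstream — spans small enough for desk-scale per-base tracks
  while leaving the change-point search a non-trivial range. Intragenic
  loci get a same-strand host whose terminal exons flank the locus, so
  hairpins sit in introns by construction.
* `sim_tracks`: plateau coverage (height 10) over each truth span plus
  optional Gaussian noise; CAGE peaks of score 50 at the truth TSS (≤5 bp
  jitter) with score-10 decoys 150 bp into the body, so TSS refinement
  must take an argmax rather than the nearest tag.
* `sim_alignments`: molecules are distinct (locus, cell, UMI) triples;
  each is emitted at least once and the remaining reads duplicate
  uniformly, so `dup_rate = 0` means exactly one read per molecule and
  the truth table equals the emitted deduplicated counts under any
  duplication level. Antisense flips exercise the strand rule.
* `sim_counts`: background genes are NB with log-normal means (meanlog
  log 1.5, sdlog 1.1) and dispersions tightly log-normal around 1.5 —
  dispersion varying smoothly with abundance is the regime the VST's
  information borrowing assumes; cell depth factors are log-normal
  (sdlog 0.35) and a logistic-in-log-depth dropout (plogis(−2 − z) on the
  standardized log depth) creates the depth confounding the biased split
  probes. Spiked genes set detection directly (Bernoulli per group) so
  effect sizes are exact: DZ 0.6 vs 0.2 detection; DE a 1.5 log2 shift of
  the positive-count mean; DP low/high NB modes (means 3 and 96, size 10)
  with low-mode weight 0.5 vs 0.9; DM an even two-mode mixture vs the low
  mode only. Positive-count means scale with each cell's depth factor
  like any real transcript — an early version omitted this and the VST's
  depth correction then smeared genuinely unimodal modes into spurious
  bimodality. The default tested panel is the spiked genes plus 16 null
  miRNA-typed features over a 200-gene coding backdrop.

What the generator does **not** emulate: ambient RNA, doublets,
batch/hashtag structure, UMI sequencing errors, gene-length or GC effects,
and real mean–variance relationships beyond NB. Passing tests therefore
demonstrate correctness of the algorithms under their stated model, not
robustness to every artifact of real droplet data.

## 9. Validation utilities

Target-set enrichment is one-sided over-representation: overlap k between
the nominal-p < 0.05 gene list and each miRNA's target set within the
tested universe, upper-tail hypergeometric p, BH across miRNAs,
significance at adjusted p < 0.1. One-sidedness mirrors the behavior of
the enrichment platforms this replaces; depletion is not screened.

The qPCR chain is: per-sample calibrator correction (subtract the sample's
calibrator offset from the cross-sample calibrator mean), then the Ct-35
detection limit, then normalization to the mean of detected reference
assays, relative expression 2^(−ΔCt), fold change as the ratio of group
means, fold regulation FC if FC ≥ 1 else −1/FC, and an unpaired two-tailed
t-test computed on the ΔCt (log) scale — the scale convention of the
vendor platforms this emulates. The correction order
(calibrator → cutoff → reference normalization) is an assumption
documented here; spike-in controls are QC-only (`qc_spikes`) and never
enter normalization.

## 10. Problem sizes and numerical choices

The test suite and acceptance script run at: exact-test enumeration over
all 2x2 tables with margins ≤ 30; 50-seed nulls at 200 genes x 300
cells/group; 20-seed power runs at 500 cells/group; subsampling at
300/500/1000/1500 cells/group from 1500/group datasets; 1e5 simulated
reads for counting. These sizes were chosen so the whole suite runs on a
single desk-scale CPU in minutes while keeping Monte-Carlo error well
inside the asserted margins. Tie-breaks (TSS refinement, change-point
splits, host selection, ranking) are all deterministic, and every
stochastic component draws through the session RNG or a sub-stream derived
from it, so a single `set.seed()` reproduces any result.

Known limitations: the expression-family permutation floor
1/(permutations+1) bounds attainable significance after BH in large
families (raise `n_perm` when testing many genes); the DZ exact test is
conservative at small counts; mixture classification needs tens of
expressing cells per group to be reliable and deliberately prefers NS/DE
over weakly supported bimodality; and the annotation stage assumes one
contiguous transcription unit per merged candidate — convergent or
read-through transcription can fuse loci that single-linkage merging
cannot separate.
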