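# mirgene

Quantifying miRNA **gene** (pri-miRNA) transcriptional activity at
single-cell resolution.

Standard scRNA-seq references barely annotate primary miRNA transcripts, so
the transcriptional activity of miRNA genes is invisible to ordinary
gene-level quantification. Poly-A-primed chemistries do, however, capture
reads along the long RNA-polymerase-II primary transcript — including its
introns — if the reference describes where that transcript actually starts
and ends. `mirgene` builds such a reference and carries the analysis through
to differential results:

1. **Annotation** — each pre-miRNA hairpin seeds a candidate primary
   transcript; the 5' end is refined to the strongest CAGE TSS within a
   window, the 3' end is extended by two-segment least-squares change-point
   analysis of nascent-transcription (GRO-seq style) coverage, candidates
   are reconciled with existing transcript models (the longer region is
   kept), overlapping same-strand candidates merge into clustered loci
   (e.g. `mir-23b~mir-24-2~mir-27b`), and each locus is classified
   *intragenic* (hairpin inside a same-strand host gene) or *intergenic*.
   The result is emitted as a GTF of single-exon pri-miRNA transcripts
   (plus optional experimentally defined alternative exon chains).
2. **Quantification** — cell-barcode/UMI-tagged alignments are assigned to
   loci by block overlap (intron-inclusive; strand-aware for droplet data,
   strandless for plate-based chemistry), deduplicated to molecule counts,
   and merged with the default gene count matrix by cell barcode.
3. **Differential distribution** — after a regularized negative-binomial
   variance-stabilizing transformation, each gene is tested between two
   condition groups in two families: the fraction of expressing cells
   (**DZ**, exact conditional test on the 2x2 detection table) and the
   expression level among expressing cells (permutation Kolmogorov–Smirnov
   test, classified **DE** / **DP** / **DM** by BIC-selected Gaussian
   mixtures: mean shift / proportion shift between shared modes / modality
   change). Each family is BH-adjusted separately.
4. **Aggregation** — per-cell-type p-values are combined across cell types
   with Fisher's method (−2·Σ ln p against χ² with 2k df) and genes passing
   a detection-rate |log2 FC| > 0.5 cut in ≥ 2 cell types are ranked.
5. **Validation & benchmarks** — hypergeometric miRNA target-set
   enrichment on a differential gene list; RT-qPCR relative expression by
   the 2^(−Avg(ΔCt)) method with calibrator correction, a Ct-35 detection
   limit and fold-regulation sign conventions; random and depth-biased
   null-split specificity benchmarks and a cell-subsampling sensitivity
   benchmark.

A synthetic-data generator (`sim_annotation`, `sim_tracks`,
`sim_alignments`, `sim_counts`) produces every input with known ground
truth — locus coordinates, read origins, per-gene effect categories — so
the entire workflow is testable without downloading any dataset.

## Worked example

```r
library(mirgene)
set.seed(1)

# -- annotation from synthetic evidence with known truth ------------------
ann  <- sim_annotation(n_intragenic = 2, n_intergenic = 2)
trk  <- sim_tracks(ann, signal = 10, noise_sd = 0)
loci <- build_mirna_loci(ann$premirna, cage = trk$cage, tracks = trk$tracks,
                         genes = ann$genes)
head(emit_gtf(loci), 3)
#> [1] "chrS  mirgene  gene        7653  10361  .  +  .  gene_id \"mir-1\"; gene_type \"miRNA_gene\";"
#> [2] "chrS  mirgene  transcript  7653  10361  .  +  .  gene_id \"mir-1\"; transcript_id \"mir-1.t1\"; gene_type \"miRNA_gene\";"
#> [3] "chrS  mirgene  exon        7653  10361  .  +  .  gene_id \"mir-1\"; transcript_id \"mir-1.t1\"; gene_type \"miRNA_gene\";"

# -- differential distribution on spiked counts ---------------------------
sim <- sim_counts(n_genes = 200, n_cells = c(500, 500))   # one spike per category
mir <- sim$counts$features$feature_id[
  sim$counts$features$feature_type == "miRNA_gene"]
dd  <- run_dd(sim$counts, sim$meta$group, test_features = mir)
head(dd[order(dd$adj_p), c("gene_id", "category", "p_value", "adj_p",
                           "rate_g1", "rate_g2", "log2_detect_fc")], 5)
#>        gene_id category  p_value    adj_p rate_g1 rate_g2 log2_detect_fc
#> 17    mir-dz-1       DZ 1.88e-35 3.76e-34   0.584   0.204         1.5083
#> 18    mir-de-2       DE 9.99e-04 6.66e-03   0.512   0.502         0.0283
#> 19    mir-dp-3       DP 9.99e-04 6.66e-03   0.526   0.522         0.0110
#> 20    mir-dm-4       DM 9.99e-04 6.66e-03   0.488   0.504        -0.0464
#> 10 mir-null-10       NS 1.30e-02 6.49e-02   0.804   0.758         0.0848

# -- concordance across cell types ----------------------------------------
ranked <- rank_concordant(list(bcell = dd, tcell = dd), min_celltypes = 2)
ranked[, c("gene_id", "fisher_statistic", "df", "combined_p", "n_pass_fc")]
#>    gene_id fisher_statistic df combined_p n_pass_fc
#> 1 mir-dz-1              320  4   5.69e-68         2
```

All four spiked effects are recovered with their true category; the
detection-rate shift (0.58 vs 0.20 expressing cells) yields a log2
detection fold change of 1.5, and the Fisher combination across two cell
types retains the gene at combined p ≈ 6e−68 with both cell types passing
the fold-change cut.

A command-line front end for shell pipelines lives at
`inst/cli/mirgene.R` (subcommands `annotate`, `count`, `dd`, `rank`,
`bench`, `simulate`, `enrich`, `qpcr`); run any subcommand with no
arguments to see its options.

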