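# m6Acoloc

Co-localization screening and site-level analyses for N6-methyladenosine
(m6A) on chromatin-associated RNAs (caRNAs).

Studies of chromatin-level m6A regulation routinely start from one
question: among the hundreds of available ChIP-seq and eCLIP peak sets
for transcription factors, histone marks and RNA-binding proteins in a
cell line, which factors co-localize with m6A peaks on caRNAs?
`m6Acoloc` implements that screen and the analyses that surround it, for
computational biologists working with peak sets (BED), gene models
(GTF), coverage tracks (bedGraph) and per-base mutation pileups.

## What it computes

**The screen.** All peak sets, m6A included, are pooled and unioned into
disjoint *reference peaks*. A binary occupancy matrix M is built with
reference peaks as rows and datasets as columns (M<sub>rc</sub> = 1 iff
dataset c overlaps reference peak r). Each factor column is scored
against the m6A column with an association index — for a, b occupied
rows and k jointly occupied rows:

- Jaccard  J = k / (a + b − k)   (default)
- Dice   D = 2k / (a + b)
- Simpson  S = k / min(a, b)
- PMI   log2[(k/N) / ((a/N)(b/N))]

and factors are ranked descending; top lists from two cell lines are
intersected (Venn partition).

**Around the screen:** region annotation of peaks
(promoter/TTS/exon/intron/intergenic, midpoint-based with strand-aware
windows), binned signal profiles at peak centres (±2.5 kb default) with
overlap-group stratification, the KAS-seq elongation index
RPKM[TSS+500, TTS) / RPKM[TSS−50, TSS+250), overlap-stratified fold-change
statistics (ECDF, 1.5×IQR box statistics, two-sided Wilcoxon rank-sum,
Pearson correlation), and single-base m6A site calling from SAC-seq
treated/untreated pileups (reference A; coverage > 5; mutant reads > 3;
frequency > 5%; frequency difference > 5%; Fisher exact p < 0.05), with
methylation-fraction quantification and k-mer context enrichment.
Seeded synthetic-data generators emulate every input with known ground
truth.

See the methods vignette (`vignettes/m6a-colocalization.Rmd`) for the
model, conventions and design choices in full.

## Worked example

A screen on synthetic data with one factor planted at Jaccard 0.8
co-occurrence with the m6A set against a 0.1 background:

```r
library(m6Acoloc)

cfg <- synthetic_config(seed = 1)
ps  <- make_peakscape(cfg)                       # m6A + 10 factor peak sets
ref <- build_reference_peaks(ps$peaksets)
om  <- build_occupancy_matrix(ref, ps$peaksets)
rk  <- rank_by_m6a_association(om, "m6A", method = "jaccard")
head(rk, 4)
#>   label     score
#> 1   F01 0.8018018
#> 2   F02 0.0989011
#> 3   F03 0.0989011
#> 4   F04 0.0989011
```

The planted factor `F01` tops the ranking at its realized Jaccard
(0.80); background factors sit at ~0.10. Downstream, fold changes at
factor-bound versus unbound peaks:

```r
fc  <- make_foldchanges(cfg)                     # bound group shifted -0.5
lab <- categorize_by_overlap(fc$features, list(bound = fc$bound_set))
xs  <- split(lab$log2fc, lab$group)
wilcoxon_rank_sum(xs[["+"]], xs[["-"]])$p.value
#> [1] 7.72e-08   (bound median -0.460 vs unbound 0.063)
```

and single-base site calling on a simulated deeply covered position with
a planted methylation fraction of 0.67:

```r
gnm   <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 2000)))
pile  <- make_sacseq_pileups(gnm,
           data.frame(chrom = "chr1", pos = 1000L, fraction = 0.67),
           synthetic_config(seed = 1, sacseq = list(depth = 1000L)))
call_sites(pile$treated, pile$untreated)[, c("pos", "methyl_fraction", "p_value")]
#>    pos methyl_fraction       p_value
#> 1 1000           0.677 2.064379e-264
```

The reported fraction is the background-subtracted frequency difference
(treated 0.691 − untreated 0.014), recovering the planted 0.67.

A thin command-line wrapper over the same functions ships in
`inst/cli/m6acoloc.R` (subcommands `simulate`, `screen`, `annotate`,
`profile`, `kas-rate`, `stratify`, `sac-call`, `sac-motif`).

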