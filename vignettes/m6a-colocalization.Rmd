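---
title: "Screening chromatin factors for co-localization with caRNA m6A"
author: "m6Acoloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chromatin factors for co-localization with caRNA m6A}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Acoloc)
library(GenomicRanges)
library(IRanges)
```

## The problem

N6-methyladenosine (m6A) on chromatin-associated RNAs (caRNAs) — in
particular promoter-associated RNAs — participates in transcriptional and
chromatin regulation. A natural first question when dissecting this layer
is *which chromatin factors sit where the m6A is*: given hundreds of
ChIP-seq and eCLIP peak sets for transcription factors, histone marks and
RNA-binding proteins in a cell line, which of them co-localize with m6A
peaks on caRNAs more than the rest?

`m6Acoloc` implements that screen and the analyses that typically surround
it in a caRNA m6A study:

* a **reference-peak occupancy matrix** and **association-index ranking**
  of factors against an m6A anchor set (the screen itself);
* **region annotation** of peaks (promoter / TTS / exon / intron /
  intergenic) and category distributions;
* **binned signal profiles** around peak centres with overlap
  stratification, and a **KAS-seq elongation index**;
* **overlap-stratified fold-change statistics** (ECDFs, box statistics,
  two-sided Wilcoxon rank-sum tests, Pearson correlation);
* **single-base m6A site calling** from SAC-seq mutation pileups with
  methylation-fraction quantification and k-mer context enrichment;
* seeded **synthetic-data generators** for every input, with ground truth.

## The screen: occupancy matrix and association indexes

All peak sets under comparison (the m6A set included) are pooled, and
overlapping intervals are unioned by single linkage into maximal disjoint
**reference peaks**. A binary matrix \(M\) is built with reference peaks
as rows and datasets as columns; \(M_{rc} = 1\) iff dataset \(c\) has at
least one interval overlapping reference peak \(r\). For two columns with
\(a\) and \(b\) occupied rows and \(k\) jointly occupied rows out of
\(N\), the package offers the Jaccard-family association indexes

\[
J = \frac{k}{a + b - k}, \qquad
D = \frac{2k}{a+b}, \qquad
S = \frac{k}{\min(a, b)}, \qquad
\mathrm{PMI} = \log_2 \frac{k/N}{(a/N)(b/N)} .
\]

The screen scores every column against the m6A anchor and sorts
descending. Jaccard is the default; the catalogue exists because studies
of this kind routinely compare several overlap indexes, and the choice is
exposed rather than hidden. Ties are broken lexicographically by label so
rankings are deterministic and input-order invariant. Indexes are
computed on reference-peak *rows*, not on base pairs: the binary-matrix
formulation asks "do these factors mark the same places", not "how many
base pairs do they share".

```{r screen}
cfg <- synthetic_config(seed = 1)
ps <- make_peakscape(cfg)
ref <- build_reference_peaks(ps$peaksets)
om <- build_occupancy_matrix(ref, ps$peaksets)
head(rank_by_m6a_association(om, "m6A"), 3)
```

Candidate lists from two cell lines are compared with
`shared_top_candidates()`, the Venn partition of the two top-n label sets.

## Interval semantics

Peaks live in `GRanges` (1-based closed, the Bioconductor convention);
BED and bedGraph input is 0-based half-open on disk and converted on
read and back on write, so round trips are exact. Overlap is half-open:
`[100,200)` and `[200,300)` do *not* overlap, and every merge operation
uses `min.gapwidth = 0` so book-ended intervals are never fused. Strand
is ignored for peak–peak overlap by default — ChIP peaks are unstranded —
with a `stranded` switch for strand-separated m6A peak sets. Chromosome
names are compared by exact string match; `normalize_chrom_names()` is
available but never applied implicitly.

Replicate m6A peak sets are merged by single-linkage clustering of all
intervals across replicates; a cluster's union interval is kept when at
least `min_support = 2` distinct replicates contribute. This is the
closest deterministic reading of the usual "peaks found in at least two
replicates were merged" practice; the exact tool flags behind such
statements are rarely printed, so the semantics are fixed here and
documented.

## Region annotation

`assign_region()` is midpoint-based with annotator-style strand-aware
windows: promoter `[TSS-1000, TSS+100)` and TTS `[TTS-100, TTS+1000)` in
transcription direction (both configurable), then exon, then intron,
with priority promoter > tts > exon > intron > intergenic and
nearest-TSS tie-breaking among genes of equal priority. Midpoint
assignment makes the partition categorical — every peak gets exactly one
label and fractions sum to 1 — which is what the downstream stacked-bar
summaries assume.

## Signal profiles and the elongation index

Coverage is consumed as bedGraph (piecewise-constant, validated disjoint,
finite, non-negative). `binned_profile()` integrates the track over
`2*flank/bin_size` fixed-width bins anchored at interval midpoints and
reports mean signal per bp per bin; windows truncated at a chromosome
start contribute zeros (stable matrix shape), and minus-strand centres
have their bin order reversed so profiles always read 5' to 3'. Profiles
default to raw track units so that worked examples are exactly
reproducible; per-million scaling is available via `norm = "cpm"`.

The KAS-seq elongation index of a gene is

\[
\frac{\mathrm{RPKM}[\mathrm{TSS}+500,\ \mathrm{TTS})}
     {\mathrm{RPKM}[\mathrm{TSS}-50,\ \mathrm{TSS}+250)}
\]

with both windows taken in transcription direction. The per-million
factor cancels, so the index is invariant to uniform rescaling of the
track. A gene shorter than 500 bp or a zero promoter-window density
yields `NA` (undefined), never an error: genome-wide sweeps should not
die on degenerate genes.

## Stratified fold-change statistics

Fold changes (e.g. m6A log2FC under factor knockdown) are *consumed*
from TSV — differential analysis itself is upstream of this package.
`categorize_by_overlap()` attaches overlap groups: `+`/`-` for one
factor set; `neither`/`one`/`both` for two (the "exactly one" reading of
a three-group design; the `pattern` scheme labels every combination
explicitly when the alternative reading is wanted). Statistics follow
the conventions such studies state: two-sided Wilcoxon rank-sum tests
(exact for small untied samples, tie-corrected normal approximation with
continuity correction otherwise — `stats::wilcox.test` semantics),
Pearson correlation with a t-distribution p-value, and box statistics
with linear-interpolation quartiles and whiskers at 1.5 x IQR. The
quartile convention matters for reproducing box plots and is therefore
fixed and documented (type-7 interpolation, not Tukey hinges). Raw
pairwise p-values are reported by default; Benjamini-Hochberg adjustment
is an explicit flag.

## SAC-seq site calling

m6A-SAC-seq chemistry induces characteristic base mutations at m6A sites;
with a treated and an untreated library, per-base mutation pileups yield
single-base calls. A position is called iff

1. the reference base is A;
2. treated coverage > 5 and treated mutant reads > 3 (strict, encoded as
   `min_cov = 6`, `min_mut = 4`);
3. treated mutation frequency > 5%;
4. treated-minus-untreated frequency difference > 5%;
5. a two-sided Fisher's exact test on the 2x2 mutant/non-mutant x
   condition table gives p < 0.05.

All frequency thresholds are strict inequalities, exactly as such filter
chains are conventionally printed; the boundary cases (coverage 5,
mutants 3, difference exactly 0.05) are excluded, and the chain is
monotone — raising any threshold can only shrink the called set. The
reported per-site methylation fraction is the background-subtracted
frequency difference; spike-in calibration curves, which the original
chemistry uses for absolute calibration, are out of scope and this
simplification is deliberate.

Fisher's exact test stands in for the somatic variant-caller p-value
such pipelines obtain from VarScan; the test is pluggable (`test`
argument). Somatic callers apply a *one-tailed* comparison, and at low
depth the tail choice is material: exact enumeration gives power 0.90
(two-sided) versus 0.95 (one-tailed) for a planted fraction of 0.20 at
depth 50 over a 1% error floor. The package defaults to the two-sided
test as the more conservative choice and exposes
`alternative = "greater"` for the somatic-caller-style comparison; the
sensitivity recovery tests run the one-tailed configuration for exactly
this reason. Positions missing from the untreated pileup are dropped by
default (the pairwise design implies both libraries observed);
`allow_missing_untreated = TRUE` keeps them with untreated counts 0/0
and no proportion test.

Sequence-context analysis is a k-mer enrichment: the k-mer centred on
each called site (reverse-complemented for minus-strand sites) is
compared against the frequency of A-centred k-mers in background
regions. This deliberately replaces full motif discovery — a ranked
k-mer table is enough to surface a planted or canonical (DRACH-like)
context and keeps the module dependency-free.

## The synthetic-data generators

Every generator is a pure function of a seeded `synthetic_config()`:
identical configurations give byte-identical outputs, and ground-truth
tables are always emitted alongside the data. The default configuration
defines the study conditions used by the whole test suite:

| component | default | what it emulates |
|---|---|---|
| genome | 2 chromosomes x 600 kb, 40 genes of ~10 kb (sd 2 kb), 2 exons each, >= 3 kb gaps | a gene-dense slice of a real genome |
| peaks | 10 factors x 200 peaks of 200 bp on a 500 bp slot grid; Jaccard targets 0.8 (planted factor) vs 0.1 (background) | the ENCODE-scale screen, scaled to desk size |
| coverage | Poisson per-bp counts, background 1, 3-fold enrichment in peaks | binding-intensity tracks |
| fold changes | bound group shifted -0.5 log2 units, sd 1, N = 300/300 | knockdown hypomethylation at bound loci |
| SAC-seq | planted fraction 0.67, 1% error, depth 100 | a highly methylated promoter-associated RNA locus |

Co-occurrence planting is exact rather than stochastic: for a target
Jaccard \(j\) and \(n\) peaks per set, \(s = \mathrm{round}(2nj/(1+j))\)
factor peaks are placed on top of distinct m6A peaks (with a small
jitter) and the rest in globally unique slots, so the realized Jaccard
\(s/(2n-s)\) matches the target to within rounding and is reported in
the truth table. The -0.5 shift, the 0.67 fraction, the 1% error floor
and the 3-fold enrichment are the effect sizes the downstream recovery
tests are calibrated against.

What the generators do *not* emulate: correlated chromatin domains,
peak-width and depth heterogeneity, mappability artifacts, overdispersed
coverage, or read-level effects (UMIs, duplicates, alignment error).
Passing recovery tests therefore demonstrate correctness of the
computations under clean planted structure, not robustness to every
pathology of real data.

## Numerical and design choices

* **Coordinates.** 1-based closed `GRanges` internally; 0-based half-open
  on disk for BED/bedGraph/pileups. TSS/TTS are stored as 0-based point
  coordinates (the 5'/3' ends in transcription direction).
* **Determinism.** Generators call `set.seed(seed + fixed offset)`; peak
  sets are sorted under a natural chromosome order regardless of input
  order; ranking ties are lexicographic.
* **Degenerate inputs.** Empty peak sets error in the screen (a screen
  without peaks is a configuration mistake); zero-variance samples error
  in `pearson_correlation`; constant samples give p = 1 with a warning in
  `wilcoxon_rank_sum`; undefined elongation rates are `NA`.
* **`alpha = 1`** disables the site-calling significance test entirely,
  giving the exact degenerate limit (all ref-A positions with positive
  frequency difference) that is useful for testing the count filters in
  isolation.
* **Problem sizes.** The test suite and the acceptance script run the
  screen at 200 peaks x 11 sets over 50-100 seeds, annotation recovery at
  500 peaks, Wilcoxon calibration at 1,000 null simulations (n = 50 per
  group) plus a 20,000-draw permutation cross-check, and SAC-seq
  simulations at up to 10,000 positions — sizes chosen so the full suite
  completes in a few minutes while keeping Monte-Carlo error well inside
  the asserted tolerances.

## Known limitations

* The screen treats every dataset as a flat peak list; peak scores,
  summit positions and per-peak significance are carried but unused.
* Midpoint-based region annotation differs from annotators that use
  whole-interval overlap; wide peaks spanning several features get the
  category of their midpoint.
* Methylation fractions are background-subtracted differences, not
  spike-in-calibrated absolute stoichiometries.
* k-mer enrichment is not motif discovery: it cannot merge degenerate
  positions into a consensus (e.g. DRACH), it only ranks exact k-mers.
* The synthetic genome is i.i.d. uniform over ACGT; composition-sensitive
  analyses (e.g. background k-mer frequencies) see an idealized genome.
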