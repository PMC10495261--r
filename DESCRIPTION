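Package: m6Acoloc
Title: Co-Localization Screening and Site-Level Analyses for Chromatin-Associated RNA m6A
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative screen that ranks chromatin factors (ChIP-seq and
    eCLIP peak sets) by co-localization with N6-methyladenosine (m6A) peaks on
    chromatin-associated RNAs, built on a binary reference-peak occupancy
    matrix and Jaccard-family association indexes, together with the
    surrounding analyses such a screen feeds: genomic-region annotation of
    peaks (promoter/exon/intron/TTS/intergenic), binned signal profiles around
    peak centres with overlap stratification, a KAS-seq elongation index,
    overlap-stratified fold-change comparisons with Wilcoxon rank-sum tests,
    and single-base m6A site calling from SAC-seq mutation pileups with
    methylation-fraction quantification and k-mer context enrichment. Seeded
    synthetic-data generators with ground truth accompany every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
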