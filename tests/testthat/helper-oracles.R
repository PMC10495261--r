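# Independent oracles and small generators used across the suite.
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# all-pairs O(n*m) overlap oracle on 0-based half-open coordinates
brute_force_overlaps <- function(a, b) {
  as <- start(a) - 1L; ae <- end(a)
  bs <- start(b) - 1L; be <- end(b)
  ac <- as.character(seqnames(a)); bc <- as.character(seqnames(b))
  vapply(seq_along(a), function(i) {
    any(bc == ac[i] & as[i] < be & bs < ae[i])
  }, logical(1L))
}

random_peakset <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                           max_width = 300L) {
  s0 <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  sort(GRanges(sample(chroms, n, replace = TRUE), IRanges(s0 + 1L, s0 + w)),
       ignore.strand = TRUE)
}

# permutation two-sided p for the Mann-Whitney U statistic
perm_wilcoxon_p <- function(x, y, n_perm = 20000L) {
  nx <- length(x); ny <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2
  dev_obs <- abs(u_obs - nx * ny / 2)
  dev <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nx + ny, nx)
    abs(sum(pooled[idx]) - nx * (nx + 1) / 2 - nx * ny / 2)
  }, 0)
  mean(dev >= dev_obs - 1e-9)
}

# two-sided Fisher p as a hypergeometric tail sum (independent of fisher.test)
fisher_oracle_p <- function(mut_t, cov_t, mut_u, cov_u) {
  k <- mut_t + mut_u
  xs <- max(0L, k - cov_u):min(k, cov_t)
  probs <- dhyper(xs, cov_t, cov_u, k)
  p_obs <- dhyper(mut_t, cov_t, cov_u, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# gene models in the read_gtf_genes() layout, built directly
make_test_gene <- function(chrom, start0, end0, strand, gene_id = "g1",
                           exon_halves = 500L) {
  g <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  exl <- GRangesList(GRanges(chrom,
                             IRanges(c(start0 + 1L, end0 - exon_halves + 1L),
                                     c(start0 + exon_halves, end0)),
                             strand = strand))
  mcols(g) <- S4Vectors::DataFrame(
    gene_id = gene_id,
    tss = if (strand == "+") start0 else end0,
    tts = if (strand == "+") end0 else start0,
    exons = exl)
  g
}

# interval integral of a piecewise-constant track, written independently
track_integral_for_test <- function(track, windows) {
  hits <- findOverlaps(windows, track)
  contrib <- (pmin(end(windows)[queryHits(hits)], end(track)[subjectHits(hits)]) -
                pmax(start(windows)[queryHits(hits)], start(track)[subjectHits(hits)]) + 1) *
    track$score[subjectHits(hits)]
  sum(contrib)
}

bed_line_set <- function(...) {
  path <- tempfile(fileext = ".bed")
  writeLines(c(...), path)
  path
}
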