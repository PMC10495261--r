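# Shared fixture builders (all constructed in code at test time).

# build an OccupancyMatrix with prescribed 0/1 columns via synthetic peaks:
# row r is reference peak [1000r, 1000r + 100); dataset c covers row r iff
# its column has a 1 there.
occ_from_columns <- function(...) {
  cols <- list(...)
  n <- length(cols[[1L]])
  ref <- GRanges("chr1", IRanges(1000 * seq_len(n) + 1L, 1000 * seq_len(n) + 100L))
  sets <- lapply(cols, function(v) ref[v == 1L])
  build_occupancy_matrix(ref, sets)
}

pileup_df <- function(pos, ref, cov, mut, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref_base = ref, coverage = cov,
             mutant_count = mut, stringsAsFactors = FALSE)
}

toy_pileups <- function() {
  # six positions exercising every site-calling filter:
  # 1: reference not A                         -> excluded
  # 2: coverage 5 (needs > 5)                  -> excluded (strict boundary)
  # 3: mutant reads 3 (needs > 3)              -> excluded (strict boundary)
  # 4: frequency difference exactly 0.05       -> excluded (strict boundary)
  # 5: 40/100 vs 1/100                         -> called, fraction 0.39
  # 6: 30/150 vs 2/150                         -> called
  treated <- pileup_df(1:6, c("G", "A", "A", "A", "A", "A"),
                       c(100L, 5L, 100L, 100L, 100L, 150L),
                       c(40L, 4L, 3L, 10L, 40L, 30L))
  untreated <- pileup_df(1:6, c("G", "A", "A", "A", "A", "A"),
                         c(100L, 100L, 100L, 100L, 100L, 150L),
                         c(1L, 0L, 0L, 5L, 1L, 2L))
  list(treated = treated, untreated = untreated)
}
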