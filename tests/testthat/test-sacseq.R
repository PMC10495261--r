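test_that("read_pileup validates the record invariants", {
  p <- tempfile()
  write.table(pileup_df(1:2, c("A", "C"), c(10L, 5L), c(3L, 0L)), p,
              sep = "\t", quote = FALSE, row.names = FALSE)
  df <- read_pileup(p)
  expect_equal(nrow(df), 2L)
  write.table(pileup_df(1, "A", 5L, 9L), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_pileup(p), "mutant_count")
  write.table(pileup_df(1, "Z", 5L, 1L), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_pileup(p), "ref_base")
})

test_that("the filter chain keeps exactly the expected toy-table survivors", {
  tp <- toy_pileups()
  sites <- call_sites(tp$treated, tp$untreated)
  expect_equal(sites$pos, c(5L, 6L))
  expect_equal(sites$methyl_fraction[1L], 0.39)
  expect_equal(sites$freq_diff[2L], 30 / 150 - 2 / 150)
})

test_that("strict thresholds exclude all boundary cases", {
  # coverage exactly 5, mutants exactly 3, diff exactly 0.05: all out
  treated <- pileup_df(1:3, "A", c(5L, 100L, 100L), c(4L, 3L, 10L))
  untreated <- pileup_df(1:3, "A", c(100L, 100L, 100L), c(0L, 0L, 5L))
  expect_equal(nrow(call_sites(treated, untreated)), 0L)
})

test_that("the proportion test matches the hypergeometric tail-sum oracle", {
  cases <- list(c(40L, 100L, 1L, 100L), c(10L, 60L, 2L, 80L),
                c(7L, 20L, 1L, 25L), c(25L, 150L, 9L, 140L))
  for (cs in cases) {
    treated <- pileup_df(1L, "A", cs[2L], cs[1L])
    untreated <- pileup_df(1L, "A", cs[4L], cs[3L])
    got <- call_sites(treated, untreated, alpha = 0.999999,
                      min_cov = 1L, min_mut = 1L, min_freq = 0, min_diff = 0)
    expect_equal(got$p_value,
                 fisher_oracle_p(cs[1L], cs[2L], cs[3L], cs[4L]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate limit returns every ref-A position with positive diff", {
  set.seed(61)
  n <- 200L
  treated <- pileup_df(seq_len(n), sample(c("A", "C", "G", "T"), n, TRUE),
                       rbinom(n, 80, 0.9), 0L)
  treated$mutant_count <- rbinom(n, treated$coverage, 0.3)
  untreated <- treated
  untreated$mutant_count <- rbinom(n, untreated$coverage, 0.3)
  got <- call_sites(treated, untreated, min_cov = 0L, min_mut = 0L,
                    min_freq = 0, min_diff = 0, alpha = 1)
  ft <- treated$mutant_count / treated$coverage
  fu <- untreated$mutant_count / untreated$coverage
  want <- which(treated$ref_base == "A" & treated$coverage > 0 &
                  untreated$coverage > 0 & ft > fu)
  expect_equal(got$pos, treated$pos[want])
})

test_that("raising any threshold never grows the called set (monotonicity)", {
  set.seed(62)
  n <- 400L
  treated <- pileup_df(seq_len(n), sample(c("A", "C"), n, TRUE, c(0.8, 0.2)),
                       50L + rbinom(n, 100L, 0.5), 0L)
  treated$mutant_count <- rbinom(n, treated$coverage,
                                 runif(n, 0, 0.4))
  untreated <- treated
  untreated$mutant_count <- rbinom(n, untreated$coverage, runif(n, 0, 0.1))
  base_args <- list(treated = treated, untreated = untreated, min_cov = 6L,
                    min_mut = 4L, min_freq = 0.05, min_diff = 0.05,
                    alpha = 0.05)
  base_set <- do.call(call_sites, base_args)$pos
  sweeps <- list(list(min_cov = 60L), list(min_mut = 10L),
                 list(min_freq = 0.15), list(min_diff = 0.15),
                 list(alpha = 0.001))
  for (sw in sweeps) {
    args <- base_args
    args[names(sw)] <- sw
    tightened <- do.call(call_sites, args)$pos
    expect_true(all(tightened %in% base_set))
  }
})

test_that("positions absent from the untreated pileup obey the pairing flag", {
  treated <- pileup_df(1:2, "A", 100L, 40L)
  untreated <- pileup_df(1L, "A", 100L, 1L)
  # default: unpaired position dropped
  expect_equal(call_sites(treated, untreated)$pos, 1L)
  # flag: kept with untreated 0/0 and no proportion test
  relaxed <- call_sites(treated, untreated, allow_missing_untreated = TRUE)
  expect_equal(relaxed$pos, c(1L, 2L))
  expect_true(is.na(relaxed$p_value[relaxed$pos == 2L]))
  expect_equal(relaxed$untreated_cov[relaxed$pos == 2L], 0L)
})

test_that("alpha outside (0, 1] is rejected", {
  tp <- toy_pileups()
  expect_error(call_sites(tp$treated, tp$untreated, alpha = 0), "alpha")
  expect_error(call_sites(tp$treated, tp$untreated, alpha = 1.2), "alpha")
})

test_that("planted methylation fractions are recovered from deep pileups", {
  errs <- vapply(1:30, function(s) {
    cfg <- synthetic_config(seed = 7000L + s,
                            sacseq = list(depth = 1000L, error = 0.01))
    gnm <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 3000)))
    sites <- data.frame(chrom = "chr1", pos = 1500L, fraction = 0.67)
    sp <- make_sacseq_pileups(gnm, sites, cfg)
    called <- call_sites(sp$treated, sp$untreated)
    called$methyl_fraction[1L] - 0.67
  }, 0)
  expect_lt(abs(mean(errs)), 0.03)
  expect_lt(max(abs(errs)), 0.06)
})

test_that("false positives stay rare and planted sites are found", {
  fp_rates <- c(); sens <- c()
  gnm <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 20000)))
  for (s in 1:10) {
    # null: 10,000 A positions, 1% error both conditions, depth 100
    cfg0 <- synthetic_config(seed = 8000L + s,
                             sacseq = list(depth = 100L, error = 0.01))
    null_sites <- data.frame(chrom = "chr1", pos = 0:9999, fraction = 0)
    sp0 <- make_sacseq_pileups(gnm, null_sites, cfg0)
    fp_rates <- c(fp_rates, nrow(call_sites(sp0$treated, sp0$untreated)) / 1e4)
    # signal: 100 planted sites at fraction 0.2, depth 50
    cfg1 <- synthetic_config(seed = 8500L + s,
                             sacseq = list(depth = 50L, error = 0.01))
    pos <- seq(10000L, 19900L, by = 100L)
    sp1 <- make_sacseq_pileups(gnm,
                               data.frame(chrom = "chr1", pos = pos, fraction = 0.2),
                               cfg1)
    # the one-tailed (somatic-caller-style) comparison is the sensitive
    # configuration at this depth; exact power 0.95 vs 0.90 two-sided
    called <- call_sites(sp1$treated, sp1$untreated, alternative = "greater")
    sens <- c(sens, mean(pos %in% called$pos))
  }
  expect_true(all(fp_rates <= 0.001))
  expect_gte(mean(sens), 0.95)
})

test_that("region methylation summaries are coverage-weighted", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 500L),
                      treated_cov = c(100L, 100L, 50L),
                      methyl_fraction = c(0.5, 0.7, 0.9))
  out <- methylation_fraction_at(sites, GRanges("chr1", IRanges(1, 100)))
  expect_equal(out$mean, 0.6)
  expect_equal(nrow(out$sites), 2L)
  # unequal weights
  sites$treated_cov <- c(300L, 100L, 50L)
  out2 <- methylation_fraction_at(sites, GRanges("chr1", IRanges(1, 100)))
  expect_equal(out2$mean, (0.5 * 300 + 0.7 * 100) / 400)
  expect_warning(out3 <- methylation_fraction_at(sites, GRanges("chr2", IRanges(1, 100))),
                 "no called sites")
  expect_true(is.na(out3$mean))
})

test_that("k-mer context enrichment finds a planted consensus", {
  set.seed(63)
  L <- 60000L
  seqchars <- sample(c("A", "C", "G", "T"), L, TRUE)
  pos <- seq(1000L, 59000L, by = 200L)      # 291 sites, 0-based centers
  planted <- seq_along(pos) <= round(0.7 * length(pos))
  for (i in seq_along(pos)) {
    ctx <- if (planted[i]) c("G", "G", "A", "C", "T")
           else c(sample(c("A", "C", "G", "T"), 2, TRUE), "A",
                  sample(c("A", "C", "G", "T"), 2, TRUE))
    seqchars[(pos[i] - 1L):(pos[i] + 3L)] <- ctx   # center at 0-based pos
  }
  gnm <- Biostrings::DNAStringSet(c(chr1 = paste(seqchars, collapse = "")))
  sites <- data.frame(chrom = "chr1", pos = pos, strand = "+")
  enr <- kmer_context_enrichment(sites, gnm, k = 5,
                                 background = GRanges("chr1", IRanges(1, L)))
  expect_equal(enr$kmer[1L], "GGACT")
  expect_gte(enr$site_freq[1L], 0.65)

  # all sites sharing one context: site frequency 1
  one <- kmer_context_enrichment(sites[planted, ], gnm, k = 5,
                                 background = GRanges("chr1", IRanges(1, L)))
  expect_equal(one$kmer, "GGACT")
  expect_equal(one$site_freq, 1)

  # minus-strand sites are reverse-complemented before counting: a genomic
  # AGTCC centered on T reads GGACT on the minus strand
  rc_pos <- seq(501L, 901L, by = 100L)
  for (p in rc_pos) seqchars[(p - 1L):(p + 3L)] <- c("A", "G", "T", "C", "C")
  gnm_rc <- Biostrings::DNAStringSet(c(chr1 = paste(seqchars, collapse = "")))
  rc <- kmer_context_enrichment(
    data.frame(chrom = "chr1", pos = rc_pos, strand = "-"), gnm_rc, k = 5,
    background = GRanges("chr1", IRanges(1, L)))
  expect_equal(rc$kmer, "GGACT")
  expect_equal(rc$site_freq, 1)

  expect_error(kmer_context_enrichment(sites, gnm, k = 4,
                                       background = GRanges("chr1", IRanges(1, L))),
               "odd")
})

test_that("sites drawn from the background show no enrichment", {
  set.seed(64)
  L <- 100000L
  gnm <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")))
  ch <- strsplit(as.character(gnm[[1]]), "")[[1]]
  apos <- which(ch == "A")
  apos <- apos[apos > 10 & apos < L - 10]
  sites <- data.frame(chrom = "chr1",
                      pos = sample(apos, 2000L) - 1L, strand = "+")
  enr <- kmer_context_enrichment(sites, gnm, k = 3,
                                 background = GRanges("chr1", IRanges(1, L)))
  # uniform draw from background: ratios hover around 1
  expect_lt(abs(mean(enr$enrichment) - 1), 0.15)
  expect_gt(min(enr$enrichment), 0.3)
  expect_lt(max(enr$enrichment), 3)
})
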