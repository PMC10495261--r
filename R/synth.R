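#' Configuration for the synthetic-data generators
#'
#' One seeded configuration drives every generator. The defaults are the
#' "paper-shaped" study conditions used throughout the test suite: two
#' chromosomes of 600 kb, 40 genes of ~10 kb with two exons each, a screen
#' of 10 factors with 200 peaks per set in which one factor is planted at
#' Jaccard 0.8 co-occurrence with the m6A set against a 0.1 background,
#' 3-fold coverage enrichment at peaks, a -0.5 log2 fold-change shift for
#' the factor-bound group (sd 1, N = 300 per group), and SAC-seq pileups
#' with a 0.67 planted methylation fraction over a 1% background mutation
#' error at depth 100.
#'
#' @param seed Integer master seed; every generator derives its RNG state
#'   from it (plus a fixed per-generator offset), so a configuration fully
#'   determines all outputs.
#' @param ... Named overrides for any of the nested defaults (`genome`,
#'   `genes`, `peaks`, `coverage`, `foldchange`, `sacseq`), each a list
#'   merged over the default.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chrom = 2L, chrom_length = 600000L),
    genes = list(n_genes = 40L, mean_length = 10000L, sd_length = 2000L,
                 min_gap = 3000L),
    peaks = list(n_factors = 10L, n_peaks = 200L, peak_width = 200L,
                 slot_spacing = 500L, jitter = 50L,
                 cooccurrence = c(0.8, rep(0.1, 9L))),
    coverage = list(background = 1.0, fold = 3.0),
    foldchange = list(shift_bound = -0.5, shift_unbound = 0, sd = 1,
                      n_bound = 300L, n_unbound = 300L),
    sacseq = list(fraction = 0.67, error = 0.01, depth = 100L)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  stopifnot(cfg$genome$n_chrom >= 1L, cfg$genome$chrom_length > 0L,
            all(cfg$peaks$cooccurrence >= 0), all(cfg$peaks$cooccurrence <= 1))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate a genome: random sequence plus gene models
#'
#' Genes are packed left to right with at least `min_gap` bp between them,
#' alternate between strands, and carry two exons (the first and last
#' 500 bp of the span) separated by one intron. Deterministic under the
#' configuration seed.
#'
#' @param config A [synthetic_config()].
#' @param dir If non-NULL, `genome.fa` and `genes.gtf` are written there.
#' @return List with `genome` (a `DNAStringSet`), `genes` (a `GRanges` in
#'   the layout of [read_gtf_genes()]) and, when written, `fasta`/`gtf`
#'   paths.
#' @export
make_genome <- function(config, dir = NULL) {
  set.seed(config$seed)
  gl <- config$genome; gn <- config$genes
  chroms <- paste0("chr", seq_len(gl$n_chrom))
  genome <- DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), gl$chrom_length, replace = TRUE),
          collapse = "")
  }, ""))
  names(genome) <- chroms

  per_chrom <- diff(round(seq(0, gn$n_genes, length.out = gl$n_chrom + 1L)))
  rows <- list()
  gi <- 0L
  for (ci in seq_len(gl$n_chrom)) {
    pos0 <- gn$min_gap
    for (j in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      len <- round(stats::rnorm(1L, gn$mean_length, gn$sd_length))
      len <- max(6000L, min(as.integer(len), 14000L))
      gap <- gn$min_gap + sample.int(2000L, 1L)
      if (pos0 + len + gap > gl$chrom_length) {
        stop("infeasible packing: chromosome too short for ", gn$n_genes,
             " genes")
      }
      rows[[gi]] <- data.frame(chrom = chroms[ci], start0 = pos0,
                               end0 = pos0 + len,
                               strand = if (gi %% 2L == 1L) "+" else "-",
                               gene_id = sprintf("g%03d", gi))
      pos0 <- pos0 + len + gap
    }
  }
  df <- do.call(rbind, rows)
  genes <- GRanges(df$chrom, IRanges(df$start0 + 1L, df$end0),
                   strand = df$strand)
  plus <- df$strand == "+"
  exl <- GRangesList(lapply(seq_len(nrow(df)), function(i) {
    GRanges(df$chrom[i],
            IRanges(c(df$start0[i] + 1L, df$end0[i] - 500L + 1L),
                    c(df$start0[i] + 500L, df$end0[i])),
            strand = df$strand[i])
  }))
  mcols(genes) <- S4Vectors::DataFrame(
    gene_id = df$gene_id,
    tss = ifelse(plus, df$start0, df$end0),
    tts = ifelse(plus, df$end0, df$start0),
    exons = exl)
  out <- list(genome = genome, genes = genes)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$fasta <- file.path(dir, "genome.fa")
    writeXStringSet(genome, out$fasta)
    out$gtf <- file.path(dir, "genes.gtf")
    write_gtf(genes, out$gtf)
  }
  out
}

#' Write gene models as GTF
#'
#' Emits one `gene` and per-exon `exon` features (1-based closed
#' coordinates), round-trippable through [read_gtf_genes()].
#'
#' @param genes Gene models in the layout of [read_gtf_genes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(genes, path) {
  fmt <- function(chrom, feat, s1, e1, strand, gid) {
    sprintf('%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, feat, s1, e1, strand, gid, paste0(gid, ".t1"))
  }
  lines <- unlist(lapply(seq_along(genes), function(i) {
    g <- genes[i]
    ex <- genes$exons[[i]]
    c(fmt(as.character(seqnames(g)), "gene", start(g), end(g),
          as.character(strand(g)), g$gene_id),
      fmt(as.character(seqnames(ex)), "exon", start(ex), end(ex),
          as.character(strand(ex)), g$gene_id))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a peak landscape with planted co-occurrence
#'
#' Generates one m6A peak set and `n_factors` factor peak sets on a global
#' slot grid. For each factor with target Jaccard `j` against the m6A set,
#' `s = round(j * 2n / (1 + j))` of its peaks are placed on top of (with a
#' small jitter) distinct m6A peaks and the rest in globally unique empty
#' slots, so the realized Jaccard `s / (2n - s)` matches the target to
#' within rounding (checked against a 0.05 tolerance). Peaks within a set
#' never overlap each other.
#'
#' @param config A [synthetic_config()].
#' @param dir If non-NULL, one BED per set and `truth_peakscape.tsv` are
#'   written there.
#' @return List with `peaksets` (named list of `GRanges`: `m6A` plus
#'   `F01..`) and `truth` (data.frame label / target / shared /
#'   realized_jaccard).
#' @export
make_peakscape <- function(config, dir = NULL) {
  set.seed(config$seed + 1L)
  pk <- config$peaks; gl <- config$genome
  n <- pk$n_peaks; w <- pk$peak_width
  if (length(pk$cooccurrence) != pk$n_factors) {
    stop("need one co-occurrence target per factor")
  }
  slot_starts <- do.call(rbind, lapply(seq_len(gl$n_chrom), function(ci) {
    s0 <- seq.int(1000L, gl$chrom_length - 1000L - w, by = pk$slot_spacing)
    data.frame(chrom = paste0("chr", ci), start0 = s0)
  }))
  shared <- round(pk$cooccurrence * 2 * n / (1 + pk$cooccurrence))
  need <- n + sum(n - shared)
  if (need > nrow(slot_starts)) {
    stop("infeasible targets: need ", need, " slots, have ", nrow(slot_starts))
  }
  slots <- slot_starts[sample.int(nrow(slot_starts), need), ]
  take <- function(k) {
    if (k == 0L) return(slots[0L, , drop = FALSE])
    out <- slots[seq_len(k), , drop = FALSE]
    slots <<- slots[-seq_len(k), , drop = FALSE]
    out
  }
  mk <- function(df) {
    sort(GRanges(df$chrom, IRanges(df$start0 + 1L, df$start0 + w)),
         ignore.strand = TRUE)
  }
  m6a_df <- take(n)
  peaksets <- list(m6A = mk(m6a_df))
  labels <- sprintf("F%02d", seq_len(pk$n_factors))
  truth <- data.frame(label = labels, target = pk$cooccurrence,
                      shared = as.integer(shared),
                      realized_jaccard = shared / (2 * n - shared))
  if (any(abs(truth$realized_jaccard - truth$target) > 0.05)) {
    stop("realized Jaccard misses its target by more than 0.05")
  }
  for (f in seq_len(pk$n_factors)) {
    s <- shared[f]
    on_m6a <- if (s > 0L) m6a_df[sample.int(n, s), , drop = FALSE] else m6a_df[0L, ]
    if (s > 0L) {
      on_m6a$start0 <- on_m6a$start0 +
        sample.int(2L * pk$jitter + 1L, s, replace = TRUE) - pk$jitter - 1L
    }
    own <- take(n - s)
    peaksets[[labels[f]]] <- mk(rbind(on_m6a, own))
  }
  out <- list(peaksets = peaksets, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(peaksets)) {
      write_bed(peaksets[[nm]], file.path(dir, paste0(nm, ".bed")))
    }
    write.table(truth, file.path(dir, "truth_peakscape.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a coverage track enriched at peaks
#'
#' Per-bp Poisson counts with mean `background` outside peaks and
#' `background x fold` inside them (fold may be a per-peak vector),
#' collapsed to bedGraph-style segments. Deterministic under the
#' configuration seed.
#'
#' @param peaks A `GRanges` of enriched regions.
#' @param config A [synthetic_config()].
#' @param fold Optional per-peak enrichment fold overriding
#'   `config$coverage$fold`.
#' @param dir If non-NULL, `coverage.bedGraph` is written there.
#' @return A track `GRanges` (zero-coverage runs omitted).
#' @export
make_coverage <- function(peaks, config, fold = NULL, dir = NULL) {
  set.seed(config$seed + 2L)
  cv <- config$coverage; gl <- config$genome
  if (is.null(fold)) fold <- rep(cv$fold, length(peaks))
  if (length(fold) == 1L) fold <- rep(fold, length(peaks))
  stopifnot(all(fold >= 1), length(fold) == length(peaks))
  segs <- list()
  for (ci in seq_len(gl$n_chrom)) {
    chrom <- paste0("chr", ci)
    lam <- rep(cv$background, gl$chrom_length)
    sel <- which(as.character(seqnames(peaks)) == chrom)
    for (i in sel) {
      lam[start(peaks)[i]:end(peaks)[i]] <- cv$background * fold[i]
    }
    counts <- stats::rpois(gl$chrom_length, lam)
    r <- rle(counts)
    ends <- cumsum(r$lengths)
    keep <- r$values > 0L
    if (any(keep)) {
      segs[[chrom]] <- GRanges(chrom,
                               IRanges(ends[keep] - r$lengths[keep] + 1L,
                                       ends[keep]),
                               score = as.numeric(r$values[keep]))
    }
  }
  track <- sort(suppressWarnings(do.call(c, unname(segs))))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bedgraph(track, file.path(dir, "coverage.bedGraph"))
  }
  track
}

#' Simulate per-feature log2 fold changes with group shifts
#'
#' Draws `log2fc ~ Normal(shift(group), sd)` for a bound and an unbound
#' feature group laid out on the slot grid, emulating differential
#' methylation under knockdown where factor-bound peaks shift down.
#'
#' @param config A [synthetic_config()].
#' @param dir If non-NULL, `foldchanges.tsv` (readable by
#'   [read_foldchanges()]) and the bound-set BED are written there.
#' @return List with `features` (a `GRanges` with `feature_id`, `log2fc`,
#'   `truth_group`), `bound_set` (a `GRanges` covering exactly the bound
#'   features, for re-deriving the groups by overlap), and `truth`
#'   (the shift per group).
#' @export
make_foldchanges <- function(config, dir = NULL) {
  set.seed(config$seed + 3L)
  fc <- config$foldchange; gl <- config$genome; w <- config$peaks$peak_width
  n <- fc$n_bound + fc$n_unbound
  spacing <- config$peaks$slot_spacing
  max_slots <- (gl$chrom_length - 2000L) %/% spacing
  per_chrom <- ceiling(n / gl$n_chrom)
  if (per_chrom > max_slots) stop("too many features for the genome")
  pos <- do.call(rbind, lapply(seq_len(gl$n_chrom), function(ci) {
    k <- min(per_chrom, n - (ci - 1L) * per_chrom)
    if (k <= 0L) return(NULL)
    data.frame(chrom = paste0("chr", ci),
               start0 = 1000L + spacing * (seq_len(k) - 1L))
  }))
  grp <- rep(c("bound", "unbound"), c(fc$n_bound, fc$n_unbound))
  grp <- sample(grp)
  shift <- ifelse(grp == "bound", fc$shift_bound, fc$shift_unbound)
  features <- GRanges(pos$chrom, IRanges(pos$start0 + 1L, pos$start0 + w))
  features$feature_id <- sprintf("pk%04d", seq_len(n))
  features$log2fc <- stats::rnorm(n, shift, fc$sd)
  features$truth_group <- grp
  bound_set <- sort_peaks(granges(features[grp == "bound"]))
  out <- list(features = features, bound_set = bound_set,
              truth = c(bound = fc$shift_bound, unbound = fc$shift_unbound))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(feature_id = features$feature_id,
                     chrom = as.character(seqnames(features)),
                     start = start(features) - 1L, end = end(features),
                     log2fc = features$log2fc)
    write.table(df, file.path(dir, "foldchanges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_bed(bound_set, file.path(dir, "bound_set.bed"))
  }
  out
}

#' Simulate SAC-seq treated/untreated mutation pileups
#'
#' For each requested position, treated mutant counts are drawn as
#' `Binomial(depth, fraction + error)` and untreated counts as
#' `Binomial(depth, error)`; rows with `fraction = 0` model unmethylated
#' background adenosines. Planted (fraction > 0) positions must be A in
#' the genome (T on the minus strand).
#'
#' @param genome A `DNAStringSet`.
#' @param sites Data.frame with `chrom`, `pos` (0-based), `fraction`
#'   (in \[0,1\]) and optionally `strand` (default `+`).
#' @param config A [synthetic_config()] (`sacseq$error`, `sacseq$depth`).
#' @param dir If non-NULL, `treated.tsv`, `untreated.tsv` and
#'   `truth_sites.tsv` are written there.
#' @return List with `treated` and `untreated` pileup data.frames (layout
#'   of [read_pileup()]) and `truth` (the input sites).
#' @export
make_sacseq_pileups <- function(genome, sites, config, dir = NULL) {
  set.seed(config$seed + 4L)
  sq <- config$sacseq
  if (is.null(sites$strand)) sites$strand <- "+"
  stopifnot(all(sites$fraction >= 0), all(sites$fraction <= 1))
  base <- vapply(seq_len(nrow(sites)), function(i) {
    as.character(subseq(genome[[sites$chrom[i]]], sites$pos[i] + 1L,
                        sites$pos[i] + 1L))
  }, "")
  expected <- ifelse(sites$strand == "-", "T", "A")
  planted <- sites$fraction > 0
  if (any(planted & base != expected)) {
    stop("planted site at a non-A position: ",
         sites$chrom[planted & base != expected][1L], ":",
         sites$pos[planted & base != expected][1L])
  }
  n <- nrow(sites)
  depth <- rep(sq$depth, n)
  p_treated <- pmin(sites$fraction + sq$error, 1)
  mk <- function(mut) {
    data.frame(chrom = sites$chrom, pos = sites$pos,
               ref_base = ifelse(sites$strand == "-",
                                 chartr("ACGT", "TGCA", base), base),
               coverage = depth, mutant_count = mut,
               strand = sites$strand, stringsAsFactors = FALSE)
  }
  treated <- mk(stats::rbinom(n, depth, p_treated))
  untreated <- mk(stats::rbinom(n, depth, sq$error))
  out <- list(treated = treated, untreated = untreated, truth = sites)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(treated, file.path(dir, "treated.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(untreated, file.path(dir, "untreated.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sites, file.path(dir, "truth_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Plant peaks in chosen region categories of a synthetic gene set
#'
#' Places peak midpoints inside the promoter window or the intron of
#' randomly chosen genes in the requested proportions — ground truth for
#' region-annotation recovery.
#'
#' @param genes Gene models from [make_genome()].
#' @param n Number of peaks.
#' @param fractions Named numeric vector over `promoter` and `intron`
#'   summing to 1.
#' @param config A [synthetic_config()] (for the seed).
#' @param peak_width Peak width in bp (default 100).
#' @return List with `peaks` (a `GRanges`) and `truth` (the planted
#'   category per peak).
#' @export
make_region_peaks <- function(genes, n, fractions = c(promoter = 0.6, intron = 0.4),
                              config = synthetic_config(), peak_width = 100L) {
  set.seed(config$seed + 5L)
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(names(fractions) %in% c("promoter", "intron")))
  cats <- sample(rep(names(fractions), round(fractions * n))[seq_len(n)])
  gidx <- sample.int(length(genes), n, replace = TRUE)
  plus <- as.character(strand(genes))[gidx] == "+"
  glen <- width(genes)[gidx]
  # offsets in transcription direction from the TSS
  off <- ifelse(cats == "promoter",
                round(stats::runif(n, -800, 50)),
                round(stats::runif(n, 600, glen - 600)))
  mid0 <- ifelse(plus, genes$tss[gidx] + off, genes$tss[gidx] - off)
  peaks <- GRanges(as.character(seqnames(genes))[gidx],
                   IRanges(mid0 - peak_width %/% 2L + 1L,
                           mid0 + peak_width %/% 2L),
                   truth_category = cats)
  peaks <- sort(peaks, ignore.strand = TRUE)
  list(peaks = peaks, truth = peaks$truth_category)
}
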