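#' Read a BED file into a GRanges peak set
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] on read (`write_bed()`
#' converts back, so round trips are loss-free). Columns 4-6 are mapped to
#' `name`, `score` and strand when present; `track`, `browser` and `#`
#' comment lines are skipped. Fields may be separated by tabs or spaces.
#'
#' @param path Path to a BED3+ file.
#' @param label Optional dataset label stored in `metadata(x)$label`
#'   (defaults to the file name without extension).
#' @return A `GRanges` sorted by (chrom, start, end), with `name` and
#'   `score` metadata columns when the file provides them. Strand is `*`
#'   where the file has `.` or no strand column.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tpk1\t5\t+", "chr1\t300\t400"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GRanges()
  } else {
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop("BED line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 columns")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    bad <- is.na(start0) | is.na(end0)
    if (any(bad)) {
      stop("BED line ", lineno[which(bad)[1L]], ": non-integer coordinate")
    }
    bad <- start0 < 0L | start0 >= end0
    if (any(bad)) {
      stop("BED line ", lineno[which(bad)[1L]],
           ": requires 0 <= start < end, got [", start0[which(bad)[1L]],
           ", ", end0[which(bad)[1L]], ")")
    }
    name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
    name[name == "."] <- NA_character_
    score <- rep(NA_real_, length(fields))
    has5 <- nf >= 5L
    score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[[`, "", 5L)))
    strand <- rep("*", length(fields))
    has6 <- nf >= 6L
    s6 <- vapply(fields[has6], `[[`, "", 6L)
    if (any(!s6 %in% c("+", "-", "."))) {
      stop("BED line ", lineno[has6][which(!s6 %in% c("+", "-", "."))[1L]],
           ": invalid strand")
    }
    s6[s6 == "."] <- "*"
    strand[has6] <- s6
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                  name = name, score = score)
  }
  gr <- sort_peaks(gr)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a peak set to a BED6 file
#'
#' Inverse of [read_bed()]: 1-based closed `GRanges` coordinates are
#' written 0-based half-open. Missing names become `.`, missing scores `0`,
#' and `*` strand is written as `.`.
#'
#' @param peaks A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  name <- if (!is.null(peaks$name)) peaks$name else rep(NA_character_, length(peaks))
  score <- if (!is.null(peaks$score)) peaks$score else rep(NA_real_, length(peaks))
  name[is.na(name)] <- "."
  score_chr <- ifelse(is.na(score), "0", format(score, trim = TRUE, scientific = FALSE))
  strand_chr <- as.character(strand(peaks))
  strand_chr[strand_chr == "*"] <- "."
  out <- paste(as.character(seqnames(peaks)), start(peaks) - 1L, end(peaks),
               name, score_chr, strand_chr, sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses `gene` and `exon` features (1-based closed GTF coordinates) into a
#' `GRanges` of gene spans carrying, per gene, the strand-aware TSS and TTS
#' as 0-based point coordinates (`tss`, `tts` metadata columns: the 5' and
#' 3' ends in transcription direction) and the exon set as a `GRangesList`
#' metadata column (`exons`).
#'
#' @param path Path to a GTF file with `gene` and `exon` features.
#' @return A `GRanges`, one range per gene, with metadata columns
#'   `gene_id`, `tss`, `tts`, `exons`.
#' @details A gene on chr1 at GTF coordinates 1001..2000 on `+` has
#'   `tss = 1000`, `tts = 2000` (0-based); on `-` the two are swapped.
#'   Genes lacking a strand or a `gene_id` attribute are an error, as are
#'   exons outside their gene span.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  if (length(genes) == 0L) stop("no 'gene' features in ", path)
  if (any(is.na(genes$gene_id)) || any(is.na(exons$gene_id))) {
    stop("GTF feature missing gene_id attribute")
  }
  if (any(as.character(strand(genes)) == "*")) {
    stop("GTF gene feature missing strand: ",
         genes$gene_id[as.character(strand(genes)) == "*"][1L])
  }
  plus <- as.character(strand(genes)) == "+"
  tss <- ifelse(plus, start(genes) - 1L, end(genes))
  tts <- ifelse(plus, end(genes), start(genes) - 1L)
  exl <- S4Vectors::split(granges(exons), factor(exons$gene_id, levels = genes$gene_id))
  within <- unlist(start(exl)) >= rep(start(genes), lengths(exl)) &
    unlist(end(exl)) <= rep(end(genes), lengths(exl))
  if (!all(within)) stop("exon outside its gene span")
  out <- granges(genes)
  mcols(out) <- S4Vectors::DataFrame(gene_id = genes$gene_id, tss = tss,
                                     tts = tts, exons = exl)
  sort(out, ignore.strand = TRUE)
}

#' Flag intervals of one peak set that overlap another
#'
#' Half-open intersection semantics: intervals \[s1,e1) and \[s2,e2) on the
#' same chromosome overlap iff `s1 < e2 && s2 < e1`; book-ended peaks do not
#' overlap. Strand is ignored by default (ChIP peaks are unstranded);
#' `stranded = TRUE` restricts overlap to matching strands, for
#' strand-separated m6A peak sets.
#'
#' @param a,b `GRanges` peak sets.
#' @param stranded Require matching strand? Default `FALSE`.
#' @return Logical vector along `a`: `TRUE` iff any interval of `b`
#'   intersects it.
#' @export
peak_overlaps <- function(a, b, stranded = FALSE) {
  # disjoint seqlevel sets are a legitimate all-FALSE case, not a warning
  suppressWarnings(overlapsAny(a, b, ignore.strand = !stranded))
}

# deterministic peak order: natural chromosome order, then start, end
sort_peaks <- function(gr) {
  sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
}

#' Merge replicate peak sets, keeping peaks supported by several replicates
#'
#' Peaks from all replicates are clustered by single-linkage overlap; each
#' cluster is collapsed to its union interval and kept iff intervals from at
#' least `min_support` distinct replicates contribute to it. With one
#' replicate and `min_support = 1` this is a plain overlap-union merge.
#'
#' @param replicates List of `GRanges`, one per biological replicate.
#' @param min_support Minimum number of distinct replicates per kept
#'   cluster. Default 2 (a peak must recur in at least two replicates).
#' @param stranded Cluster per strand? Default `FALSE`.
#' @return A `GRanges` of union intervals with a `support` metadata column.
#' @export
merge_replicate_peaks <- function(replicates, min_support = 2L, stranded = FALSE) {
  if (!is.list(replicates) && !methods::is(replicates, "GRangesList")) {
    replicates <- list(replicates)
  }
  if (min_support < 1L) stop("min_support must be >= 1")
  if (length(replicates) < min_support) {
    stop("need at least min_support = ", min_support, " replicates, got ",
         length(replicates))
  }
  rep_id <- rep(seq_along(replicates), vapply(replicates, length, 0L))
  pooled <- suppressWarnings(do.call(c, unname(lapply(replicates, granges))))
  merged <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                  ignore.strand = !stranded,
                                  with.revmap = TRUE)
  support <- vapply(merged$revmap, function(i) length(unique(rep_id[i])), 0L)
  merged$revmap <- NULL
  merged$support <- support
  sort_peaks(merged[support >= min_support])
}

#' Normalize chromosome naming between peak sets
#'
#' Chromosome names are compared by exact string match throughout the
#' package; this helper (off by default everywhere) strips or adds a `chr`
#' prefix so that sets from different providers can be made comparable
#' explicitly.
#'
#' @param x A `GRanges`.
#' @param style `"chr"` to ensure a chr prefix, `"plain"` to strip it.
#' @return `x` with renamed seqlevels.
#' @export
normalize_chrom_names <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  lv <- GenomeInfoDb::seqlevels(x)
  new <- if (style == "chr") ifelse(grepl("^chr", lv), lv, paste0("chr", lv))
         else sub("^chr", "", lv)
  GenomeInfoDb::seqlevels(x) <- as.character(new)
  x
}
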