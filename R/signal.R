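#' Read a bedGraph coverage track
#'
#' Loads a 4-column bedGraph into a `GRanges` with a `score` column —
#' piecewise-constant coverage with disjoint, sorted segments and finite
#' non-negative values. Overlapping input segments are rejected.
#'
#' @param path Path to a bedGraph file.
#' @return A sorted `GRanges` with `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  validate_track(sort(gr))
}

#' Write a coverage track as bedGraph
#' @param track A track `GRanges` (see [read_bedgraph()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

validate_track <- function(track) {
  if (is.null(track$score)) stop("track has no score column")
  if (any(!is.finite(track$score)) || any(track$score < 0)) {
    stop("track values must be finite and >= 0")
  }
  if (!isDisjoint(track)) {
    ov <- findOverlaps(track, drop.self = TRUE)
    bad <- track[queryHits(ov)[1L]]
    stop("overlapping bedGraph segments at ", seqnames(bad), ":",
         start(bad) - 1L, "-", end(bad))
  }
  track
}

#' Total signal of a track
#'
#' Sum of value x segment length over the whole track, the denominator of
#' per-million scaling.
#' @param track A track `GRanges`.
#' @return A single number.
#' @export
track_total_signal <- function(track) {
  sum(as.numeric(width(track)) * track$score)
}

# integral of the track over each window (sum of value x overlap length)
track_integral <- function(track, windows) {
  hits <- findOverlaps(windows, track, ignore.strand = TRUE)
  if (length(hits) == 0L) return(numeric(length(windows)))
  ov <- pmin(end(windows)[queryHits(hits)], end(track)[subjectHits(hits)]) -
    pmax(start(windows)[queryHits(hits)], start(track)[subjectHits(hits)]) + 1L
  contrib <- as.numeric(ov) * track$score[subjectHits(hits)]
  out <- numeric(length(windows))
  agg <- rowsum(contrib, queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Binned signal profile around peak centres
#'
#' Mean signal per bp in fixed-width bins across windows of `+/- flank` bp
#' anchored at the midpoints of `centers` — the matrix behind average
#' profiles and heatmaps of binding intensity at peak centres. Windows
#' truncated at a chromosome start contribute 0 for out-of-range bp (the
#' matrix keeps a stable shape); minus-strand centers have their bin order
#' reversed so that bins always run 5' to 3'.
#'
#' @param track A track `GRanges` (see [read_bedgraph()]).
#' @param centers A `GRanges`; interval midpoints are the anchor points.
#' @param flank Half-window in bp (default 2500); must be divisible by
#'   `bin_size`.
#' @param bin_size Bin width in bp (default 50).
#' @param norm `"none"` (raw mean value per bp, the default) or `"cpm"`
#'   (scaled by 1e6 / total track signal).
#' @return An object of class `ProfileMatrix`: list with `values`
#'   (centers x bins matrix), `average_profile` (per-bin mean over
#'   centers), `bin_mid` (bin midpoint offsets from the center, bp),
#'   `flank`, `bin_size`.
#' @export
binned_profile <- function(track, centers, flank = 2500L, bin_size = 50L,
                           norm = c("none", "cpm")) {
  norm <- match.arg(norm)
  if (flank %% bin_size != 0L) stop("flank must be divisible by bin_size")
  validate_track(track)
  nbins <- as.integer(2L * flank / bin_size)
  n <- length(centers)
  mid0 <- floor((start(centers) - 1L + end(centers)) / 2)
  offsets <- seq.int(-flank, flank - bin_size, by = bin_size)
  idx <- rep(seq_len(n), each = nbins)
  s0 <- mid0[idx] + rep(offsets, times = n)
  e0 <- s0 + bin_size
  valid <- e0 >= 1L
  vals <- numeric(n * nbins)
  if (any(valid)) {
    wins <- GRanges(as.character(seqnames(centers))[idx][valid],
                    IRanges(pmax(s0[valid], 0L) + 1L, e0[valid]))
    vals[valid] <- track_integral(track, wins) / bin_size
  }
  m <- matrix(vals, nrow = n, ncol = nbins, byrow = TRUE)
  minus <- as.character(strand(centers)) == "-"
  if (any(minus)) m[minus, ] <- m[minus, nbins:1, drop = FALSE]
  if (norm == "cpm") {
    tot <- track_total_signal(track)
    if (tot <= 0) stop("cannot per-million scale a zero-signal track")
    m <- m * 1e6 / tot
  }
  structure(list(values = m,
                 average_profile = colMeans(m),
                 bin_mid = offsets + bin_size / 2,
                 flank = flank, bin_size = bin_size),
            class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat("ProfileMatrix:", nrow(x$values), "centers x", ncol(x$values),
      "bins of", x$bin_size, "bp (flank", x$flank, "bp)\n")
  invisible(x)
}

#' Group-averaged profiles around peak centres
#'
#' [binned_profile()] computed per group of centers (e.g. peaks
#' overlapping m6A versus not), returning one average profile per group.
#'
#' @param track,centers,flank,bin_size,norm As in [binned_profile()].
#' @param groups Group label per center (no missing values).
#' @return List with `profiles` (named list of per-bin average vectors),
#'   `sizes` (centers per group), `bin_mid`.
#' @export
stratified_profile <- function(track, centers, groups, flank = 2500L,
                               bin_size = 50L, norm = c("none", "cpm")) {
  if (length(groups) != length(centers) || anyNA(groups)) {
    stop("every center must carry a group label")
  }
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  profs <- lapply(lv, function(g) {
    binned_profile(track, centers[groups == g], flank = flank,
                   bin_size = bin_size, norm = norm)$average_profile
  })
  names(profs) <- lv
  list(profiles = profs,
       sizes = vapply(lv, function(g) sum(groups == g), 0L),
       bin_mid = seq.int(-flank, flank - bin_size, by = bin_size) + bin_size / 2)
}

#' Reads per kilobase per million (RPKM) over intervals
#'
#' Signal in the interval (integral of the track) per kilobase of interval,
#' per million units of total track signal.
#'
#' @param track A track `GRanges` with positive total signal.
#' @param intervals A `GRanges`.
#' @return Numeric vector along `intervals`.
#' @export
rpkm <- function(track, intervals) {
  validate_track(track)
  tot <- track_total_signal(track)
  if (tot <= 0) stop("total track signal is zero; RPKM undefined")
  sig <- track_integral(track, intervals)
  (sig / (width(intervals) / 1000)) / (tot / 1e6)
}

#' KAS-seq elongation rate per gene
#'
#' Ratio of gene-body read density to promoter-proximal read density: RPKM
#' over \[TSS+500, TTS) divided by RPKM over \[TSS-50, TSS+250), both in
#' transcription direction (strand-aware genome windows). The per-million
#' factor cancels, so the statistic is invariant to uniform rescaling of
#' the track. Genes whose body window is empty (shorter than 500 bp)
#' yield `NA` with a warning; a zero promoter-window density yields `NA`
#' (undefined, not an error).
#'
#' @param genes Gene models from [read_gtf_genes()].
#' @param track A track `GRanges`.
#' @param body_offset Offset of the body window start downstream of the
#'   TSS (default 500 bp).
#' @param prom_up,prom_down Promoter window, bp up/downstream of the TSS
#'   (defaults 50 and 250).
#' @return Numeric vector along `genes` (NA where undefined).
#' @export
elongation_rate <- function(genes, track, body_offset = 500L,
                            prom_up = 50L, prom_down = 250L) {
  validate_track(track)
  plus <- as.character(strand(genes)) == "+"
  body_s0 <- ifelse(plus, genes$tss + body_offset, genes$tts)
  body_e0 <- ifelse(plus, genes$tts, genes$tss - body_offset)
  prom_s0 <- ifelse(plus, genes$tss - prom_up, genes$tss - prom_down)
  prom_e0 <- ifelse(plus, genes$tss + prom_down, genes$tss + prom_up)

  out <- rep(NA_real_, length(genes))
  ok <- body_e0 > body_s0
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) with body shorter than ", body_offset,
            " bp; elongation rate undefined")
  }
  if (!any(ok)) return(out)
  chr <- as.character(seqnames(genes))[ok]
  body <- GRanges(chr, IRanges(body_s0[ok] + 1L, body_e0[ok]))
  prom <- GRanges(chr, IRanges(pmax(prom_s0[ok], 0L) + 1L, prom_e0[ok]))
  body_d <- track_integral(track, body) / width(body)
  prom_d <- track_integral(track, prom) / width(prom)
  r <- ifelse(prom_d > 0, body_d / prom_d, NA_real_)
  out[ok] <- r
  out
}
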