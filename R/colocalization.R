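#' Pool peak sets into disjoint reference peaks
#'
#' All intervals from all input sets (including the m6A set) are pooled and
#' overlapping intervals are unioned by single linkage into maximal disjoint
#' reference peaks — the rows of the occupancy matrix. Book-ended (touching)
#' intervals are not merged.
#'
#' @param peaksets List of `GRanges`.
#' @return A disjoint, sorted, unstranded `GRanges`.
#' @export
build_reference_peaks <- function(peaksets) {
  if (!is.list(peaksets)) peaksets <- list(peaksets)
  if (sum(vapply(peaksets, length, 0L)) == 0L) {
    stop("all input peak sets are empty")
  }
  pooled <- suppressWarnings(do.call(c, unname(lapply(peaksets, granges))))
  sort_peaks(GenomicRanges::reduce(pooled, min.gapwidth = 0L, ignore.strand = TRUE))
}

#' Build the binary reference-peak occupancy matrix
#'
#' Rows are reference peaks, columns are datasets (histone marks,
#' transcription factors, RBPs, the m6A set); entry (r, c) is 1 iff dataset
#' c has at least one interval overlapping reference peak r.
#'
#' @param reference Disjoint `GRanges` of reference peaks
#'   (see [build_reference_peaks()]).
#' @param datasets Named list of `GRanges`; names are the column labels and
#'   must be unique.
#' @param stranded Passed to [peak_overlaps()]. Default `FALSE`.
#' @return An object of class `OccupancyMatrix`: a list with `reference`
#'   (the row `GRanges`) and `entries` (integer 0/1 matrix with dataset
#'   labels as colnames).
#' @export
build_occupancy_matrix <- function(reference, datasets, stranded = FALSE) {
  if (is.null(names(datasets)) || anyNA(names(datasets)) ||
      any(names(datasets) == "")) {
    stop("datasets must be a named list (labels become matrix columns)")
  }
  if (anyDuplicated(names(datasets))) {
    stop("duplicate dataset labels: ",
         paste(unique(names(datasets)[duplicated(names(datasets))]), collapse = ", "))
  }
  if (!isDisjoint(reference)) stop("reference peaks must be disjoint")
  entries <- vapply(datasets, function(d) {
    as.integer(peak_overlaps(reference, d, stranded = stranded))
  }, integer(length(reference)))
  if (length(reference) == 1L) entries <- matrix(entries, nrow = 1L,
                                                 dimnames = list(NULL, names(datasets)))
  structure(list(reference = reference, entries = entries),
            class = "OccupancyMatrix")
}

#' @export
print.OccupancyMatrix <- function(x, ...) {
  cat("OccupancyMatrix:", nrow(x$entries), "reference peaks x",
      ncol(x$entries), "datasets\n")
  cat("column sums:\n")
  print(colSums(x$entries))
  invisible(x)
}

#' Association index between two occupancy-matrix columns
#'
#' With a = |rows where column A is 1|, b likewise for B, k = |rows where
#' both are 1| and N the row count:
#' \describe{
#'   \item{jaccard}{k / (a + b - k); 0 when k = 0.}
#'   \item{dice}{2k / (a + b); 0 when k = 0.}
#'   \item{simpson}{k / min(a, b) (overlap coefficient).}
#'   \item{pmi}{log2((k/N) / ((a/N)(b/N))), pointwise mutual information;
#'     defined only for k > 0.}
#' }
#' All indexes are symmetric in the two columns; jaccard, dice and simpson
#' lie in \[0, 1\] with jaccard <= dice and jaccard <= simpson.
#'
#' @param matrix An `OccupancyMatrix`.
#' @param col_a,col_b Column labels.
#' @param method One of `"jaccard"` (default), `"dice"`, `"simpson"`,
#'   `"pmi"`.
#' @return A single number.
#' @export
association_index <- function(matrix, col_a, col_b,
                              method = c("jaccard", "dice", "simpson", "pmi")) {
  method <- match.arg(method)
  m <- matrix$entries
  for (cl in c(col_a, col_b)) {
    if (!cl %in% colnames(m)) stop("no such column: ", cl)
  }
  va <- m[, col_a] == 1L
  vb <- m[, col_b] == 1L
  a <- sum(va); b <- sum(vb); k <- sum(va & vb); N <- nrow(m)
  switch(method,
    jaccard = if (k == 0L) 0 else k / (a + b - k),
    dice = if (k == 0L) 0 else 2 * k / (a + b),
    simpson = {
      if (a == 0L || b == 0L) stop("simpson undefined for an empty column")
      k / min(a, b)
    },
    pmi = {
      if (a == 0L || b == 0L) stop("pmi undefined for an empty column")
      if (k == 0L) stop("pmi undefined for k = 0 (no co-occurrence)")
      log2((k / N) / ((a / N) * (b / N)))
    })
}

#' Rank datasets by association with the m6A column
#'
#' Scores every non-anchor column of the occupancy matrix against the m6A
#' column with [association_index()] and sorts the results in decreasing
#' order; ties are broken lexicographically by label for determinism.
#'
#' @param matrix An `OccupancyMatrix`.
#' @param m6a_col Label of the anchor (m6A) column.
#' @param method Index name passed to [association_index()].
#' @return A data.frame of class `AssociationRanking` with columns `label`
#'   and `score`, plus attributes `method` and `anchor`.
#' @export
rank_by_m6a_association <- function(matrix, m6a_col, method = "jaccard") {
  labs <- colnames(matrix$entries)
  if (!m6a_col %in% labs) stop("anchor column not in matrix: ", m6a_col)
  others <- setdiff(labs, m6a_col)
  scores <- vapply(others, function(cl) {
    association_index(matrix, cl, m6a_col, method = method)
  }, 0)
  ord <- order(-scores, others)
  out <- data.frame(label = others[ord], score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "anchor") <- m6a_col
  class(out) <- c("AssociationRanking", class(out))
  out
}

#' Intersect the top candidates of two rankings
#'
#' The Venn partition of the top-n label sets of two association rankings,
#' e.g. the candidates shared between two cell lines.
#'
#' @param ranking_a,ranking_b `AssociationRanking` objects
#'   (see [rank_by_m6a_association()]).
#' @param top_n How many top labels to take from each ranking.
#' @return A list with `shared`, `only_a`, `only_b` (each a sorted
#'   character vector).
#' @export
shared_top_candidates <- function(ranking_a, ranking_b, top_n) {
  if (top_n > nrow(ranking_a) || top_n > nrow(ranking_b)) {
    stop("top_n exceeds ranking length")
  }
  ta <- ranking_a$label[seq_len(top_n)]
  tb <- ranking_b$label[seq_len(top_n)]
  list(shared = sort(intersect(ta, tb)),
       only_a = sort(setdiff(ta, tb)),
       only_b = sort(setdiff(tb, ta)))
}

#' Export an occupancy matrix as sparse triplets plus a row BED
#'
#' Writes the nonzero entries as an MTX-style triplet TSV (row, col, 1)
#' with a label header, and the reference peaks as BED, so the screen's
#' matrix can be consumed outside R.
#'
#' @param matrix An `OccupancyMatrix`.
#' @param triplets_path,bed_path Output paths.
#' @return Invisibly, the triplet path.
#' @export
write_occupancy_matrix <- function(matrix, triplets_path, bed_path) {
  idx <- which(matrix$entries == 1L, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1L],
                   label = colnames(matrix$entries)[idx[, 2L]],
                   value = 1L)
  df <- df[order(df$row, df$label), ]
  write.table(df, triplets_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(matrix$reference, bed_path)
  invisible(triplets_path)
}
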