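#' Label features by overlap with factor peak sets
#'
#' Categorizes per-feature records (e.g. m6A peaks carrying a log2 fold
#' change) by which factor peak sets their interval overlaps. With one
#' factor set the groups are `+` / `-`; with two or more, the default
#' `"count"` scheme yields `neither`, `one`, `both` (or `"0".."k"` counts
#' beyond two sets), and the `"pattern"` scheme labels each combination
#' explicitly (e.g. `RBFOX2+RBM15`, `RBFOX2`, `none`).
#'
#' @param features A `GRanges` of feature loci (any metadata columns, e.g.
#'   `log2fc`, are carried through).
#' @param factor_sets Named list of `GRanges`.
#' @param scheme `"count"` (default) or `"pattern"`.
#' @param stranded Passed to [peak_overlaps()].
#' @return `features` with a `group` metadata column added; group sizes are
#'   in `attr(, "group_sizes")`.
#' @export
categorize_by_overlap <- function(features, factor_sets,
                                  scheme = c("count", "pattern"),
                                  stranded = FALSE) {
  scheme <- match.arg(scheme)
  if (!is.list(factor_sets)) factor_sets <- list(factor_sets)
  if (is.null(names(factor_sets))) {
    names(factor_sets) <- paste0("set", seq_along(factor_sets))
  }
  flags <- vapply(factor_sets, function(s) {
    peak_overlaps(features, s, stranded = stranded)
  }, logical(length(features)))
  if (length(features) == 1L) flags <- matrix(flags, nrow = 1L)
  k <- length(factor_sets)
  if (k == 1L) {
    group <- ifelse(flags[, 1L], "+", "-")
    lev <- c("-", "+")
  } else if (scheme == "count") {
    nhit <- rowSums(flags)
    if (k == 2L) {
      group <- c("neither", "one", "both")[nhit + 1L]
      lev <- c("neither", "one", "both")
    } else {
      group <- as.character(nhit)
      lev <- as.character(0:k)
    }
  } else {
    group <- apply(flags, 1L, function(f) {
      if (!any(f)) "none" else paste(names(factor_sets)[f], collapse = "+")
    })
    lev <- sort(unique(group))
  }
  features$group <- factor(group, levels = lev)
  attr(features, "group_sizes") <- table(features$group)
  features
}

#' Empirical cumulative distribution as step points
#'
#' The right-continuous ECDF of a sample as sorted (value, cumulative
#' fraction) pairs — the cumulative-curve representation used to compare
#' fold-change distributions between overlap groups.
#'
#' @param values Non-empty numeric vector.
#' @return A data.frame with columns `value` (sorted unique values) and
#'   `fraction` (cumulative fraction, ending at 1).
#' @export
ecdf_points <- function(values) {
  if (length(values) == 0L) stop("ecdf of an empty sample")
  fn <- stats::ecdf(values)
  v <- sort(unique(values))
  data.frame(value = v, fraction = fn(v))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Wraps [stats::wilcox.test()]: exact enumeration for small untied
#' samples, otherwise the normal approximation with tie-corrected variance
#' and continuity correction. If every value in both samples is identical
#' the test is degenerate and `p = 1` is returned with a warning.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `statistic` (the Mann-Whitney U for `x`) and
#'   `p.value` (two-sided, in (0, 1\]).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = min(wt$p.value, 1))
}

#' Box-plot statistics with interpolated quartiles and 1.5 x IQR whiskers
#'
#' Quartiles by linear interpolation of order statistics
#' ([stats::quantile()] type 7); whiskers extend to the most extreme data
#' points within 1.5 x IQR of the quartiles, and points beyond are
#' outliers.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}

#' Pearson correlation with two-sided p-value
#'
#' Wraps [stats::cor.test()]; p from the t distribution with n - 2 degrees
#' of freedom. Zero variance in either vector is an error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r` and `p.value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}

#' Per-group summary of overlap-stratified fold changes
#'
#' One-stop summary behind cumulative-curve/box-plot figures: per-group N,
#' box statistics, and all pairwise two-sided Wilcoxon rank-sum p-values
#' (optionally Benjamini-Hochberg adjusted).
#'
#' @param features Output of [categorize_by_overlap()] with a numeric
#'   `log2fc` metadata column.
#' @param adjust Apply BH adjustment to the pairwise p-values? Default
#'   `FALSE` (raw pairwise p-values).
#' @return List with `groups` (data.frame of n/median/q1/q3 per group) and
#'   `pairwise` (data.frame group_a, group_b, p).
#' @export
stratified_summary <- function(features, adjust = FALSE) {
  if (is.null(features$group) || is.null(features$log2fc)) {
    stop("features need 'group' and 'log2fc' metadata columns")
  }
  sp <- split(features$log2fc, features$group)
  sp <- sp[lengths(sp) > 0L]
  gstats <- do.call(rbind, lapply(names(sp), function(g) {
    b <- boxplot_stats(sp[[g]])
    data.frame(group = g, n = b$n, median = b$median, q1 = b$q1, q3 = b$q3)
  }))
  prs <- if (length(sp) >= 2L) utils::combn(names(sp), 2L) else NULL
  pairwise <- if (!is.null(prs)) {
    p <- apply(prs, 2L, function(gg) {
      wilcoxon_rank_sum(sp[[gg[1L]]], sp[[gg[2L]]])$p.value
    })
    if (adjust) p <- stats::p.adjust(p, method = "BH")
    data.frame(group_a = prs[1L, ], group_b = prs[2L, ], p = p)
  } else {
    data.frame(group_a = character(), group_b = character(), p = numeric())
  }
  list(groups = gstats, pairwise = pairwise)
}

#' Read a per-feature log2 fold-change table
#'
#' Tab-separated input with columns `feature_id`, `chrom`, `start`, `end`
#' (0-based half-open) and `log2fc` — e.g. differential-methylation or
#' differential-expression output computed upstream.
#'
#' @param path Path to the TSV (with header).
#' @return A `GRanges` with `feature_id` and `log2fc` metadata columns.
#' @export
read_foldchanges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "chrom", "start", "end", "log2fc")
  if (!all(need %in% names(df))) {
    stop("fold-change table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$log2fc))) stop("non-finite log2fc values")
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  gr$feature_id <- df$feature_id
  gr$log2fc <- df$log2fc
  gr
}
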