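# Repository-scale summaries over a joined quality + metadata table:
# top-N category count tables with printed percentages, histograms (linear
# or log10, optionally faceted by a metadata category), threshold fractions,
# simple moments, and quarterly box-plot tables. All summaries are pure
# functions of the joined table; re-running yields identical output. The
# package emits plot-ready tables; rendering is left to the caller.

#' Percentage rounded to one decimal
#'
#' `100 * numerator / denominator`, rounded half away from zero to one
#' decimal — the convention under which published repository percentages
#' (e.g. 426841 of 1171313 = 36.4) reproduce exactly from their counts.
#'
#' @param numerator,denominator counts, `numerator <= denominator`,
#'   `denominator > 0`.
#' @return percentage with one decimal.
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("zero or negative denominator")
  if (any(numerator > denominator)) stop("numerator exceeds denominator")
  round_half_up(100 * numerator / denominator, 1)
}

#' Top-N category count table
#'
#' Counts distinct values of a categorical column, with `NA` grouped as
#' `"(missing)"`. Rows are sorted by descending count (ties broken
#' lexically); the first `top_n` categories are kept and the remainder is
#' collapsed into an `"other"` row. Percentages are of the full corpus
#' total, rounded per [percentage()].
#'
#' @param joined joined data.frame.
#' @param field category column name.
#' @param top_n number of categories to keep (default 20).
#' @return data.frame (category, count, percent) with attribute
#'   `corpus_total`.
#' @export
category_counts <- function(joined, field, top_n = 20L) {
  if (!field %in% names(joined)) stop("unknown field: ", field)
  x <- as.character(joined[[field]])
  x[is.na(x) | !nzchar(x)] <- "(missing)"
  tab <- table(x)
  df <- data.frame(category = names(tab), count = as.numeric(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$category), , drop = FALSE]
  total <- sum(df$count)
  if (nrow(df) > top_n) {
    head_df <- df[seq_len(top_n), , drop = FALSE]
    other <- data.frame(category = "other",
                        count = sum(df$count[-seq_len(top_n)]),
                        stringsAsFactors = FALSE)
    df <- rbind(head_df, other)
  }
  df$percent <- percentage(df$count, total)
  rownames(df) <- NULL
  attr(df, "corpus_total") <- total
  df
}

#' Histogram table
#'
#' Bins values into half-open equal-width bins `[lo, hi)` on a linear or
#' log10 scale, optionally faceted by a category vector (the color-coding
#' facet of repository-distribution figures). On the log10 scale,
#' non-positive values are excluded and counted; non-finite values are
#' always excluded and counted. The topmost bin is closed so the maximum is
#' not dropped.
#'
#' @param values numeric vector.
#' @param scale `"linear"` or `"log10"`.
#' @param bins bin count (equal-width on the chosen scale), or a vector of
#'   explicit bin edges on that scale (length >= 2).
#' @param facet optional category vector parallel to `values`.
#' @return data.frame (bin_lo, bin_hi, facet?, count) on the original value
#'   scale, with attribute `excluded` = list(non_finite, non_positive).
#' @export
histogram_table <- function(values, scale = c("linear", "log10"), bins = 30L,
                            facet = NULL) {
  scale <- match.arg(scale)
  keep <- is.finite(values)
  n_nonfinite <- sum(!keep)
  n_nonpositive <- 0L
  if (scale == "log10") {
    pos <- keep & values > 0
    n_nonpositive <- sum(keep & values <= 0)
    keep <- pos
  }
  x <- values[keep]
  if (length(x) == 0L) stop("no finite values to bin")
  f <- if (!is.null(facet)) as.character(facet)[keep]
  if (scale == "log10") x <- log10(x)
  edges <- if (length(bins) > 1L) as.numeric(bins) else {
    stopifnot(bins >= 1L)
    rng <- range(x)
    if (rng[1L] == rng[2L]) rng[2L] <- rng[1L] + 1
    seq(rng[1L], rng[2L], length.out = as.integer(bins) + 1L)
  }
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must increase")
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  oob <- idx == 0L | idx >= length(edges) & x > edges[length(edges)]
  if (any(oob)) stop("values outside explicit bin edges")
  back <- function(e) if (scale == "log10") 10^e else e
  nb <- length(edges) - 1L
  if (is.null(f)) {
    cnt <- tabulate(idx, nbins = nb)
    out <- data.frame(bin_lo = back(edges[seq_len(nb)]),
                      bin_hi = back(edges[-1L]), count = cnt)
  } else {
    lev <- sort(unique(f))
    out <- do.call(rbind, lapply(lev, function(l) {
      cnt <- tabulate(idx[f == l], nbins = nb)
      data.frame(bin_lo = back(edges[seq_len(nb)]),
                 bin_hi = back(edges[-1L]), facet = l, count = cnt)
    }))
  }
  attr(out, "excluded") <- list(non_finite = n_nonfinite,
                                non_positive = n_nonpositive)
  out
}

#' Fraction of values strictly below a threshold
#'
#' The repository-style threshold statistic, e.g. the share of experiments
#' with N content below 1 percent.
#'
#' @param values nonempty numeric vector.
#' @param threshold cutoff; comparison is strict (`<`).
#' @return list with `count` below the threshold and `percent` (one
#'   decimal, per [percentage()]).
#' @export
threshold_fraction <- function(values, threshold) {
  if (length(values) == 0L) stop("no values")
  n <- sum(values < threshold)
  list(count = n, percent = percentage(n, length(values)))
}

#' Mean and lower median of a numeric vector
#'
#' @param values nonempty numeric vector.
#' @return list with `mean` (arithmetic) and `median` (lower median: on an
#'   even count, the lower of the two middle values).
#' @export
distribution_moments <- function(values) {
  if (length(values) == 0L) stop("no values")
  list(mean = mean(values), median = lower_median(values))
}

quarter_label <- function(dates) {
  d <- as.Date(dates)
  paste0(format(d, "%Y"), "-Q", (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L)
}

#' Quarterly box-plot table
#'
#' Groups a value column by calendar quarter of a date column and emits, per
#' quarter with data: n, the five-number summary (min, lower quartile,
#' lower median, upper quartile, max; quartiles by the lower nearest-rank
#' rule) and the mean — the table behind quarterly time-series box plots
#' where printed n annotates each box and a line connects the means. Rows
#' with an unparseable or missing date are excluded and counted in the
#' `excluded` attribute; empty quarters are omitted.
#'
#' @param joined data.frame.
#' @param value_field numeric column to summarize.
#' @param date_field column parseable by [as.Date()].
#' @return data.frame (quarter, n, min, q1, median, q3, max, mean) sorted by
#'   quarter.
#' @export
quarterly_boxplots <- function(joined, value_field, date_field = "date") {
  stopifnot(value_field %in% names(joined), date_field %in% names(joined))
  v <- as.numeric(joined[[value_field]])
  d <- suppressWarnings(as.Date(as.character(joined[[date_field]])))
  keep <- !is.na(d) & is.finite(v)
  if (!any(keep)) stop("no rows with a parseable date")
  q <- quarter_label(d[keep])
  v <- v[keep]
  out <- do.call(rbind, lapply(sort(unique(q)), function(qq) {
    x <- v[q == qq]
    data.frame(quarter = qq, n = length(x), min = min(x),
               q1 = rank_percentile(x, 0.25), median = lower_median(x),
               q3 = rank_percentile(x, 0.75), max = max(x), mean = mean(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(!keep)
  out
}
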