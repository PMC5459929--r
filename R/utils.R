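# Shared numeric conventions. Stated once, used everywhere so that every
# oracle in the test suite is unambiguous:
#   * percentiles use the lower nearest-rank rule: rank = ceiling(p * n)
#   * the median of an even-sized sample is the lower of the two middle values
#   * printed percentages round half away from zero to one decimal

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (so 0.05 -> 0.1),
#' the convention under which the printed repository percentages are exact.
#' Base [round()] uses banker's rounding and is not suitable here.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Lower nearest-rank percentile of an unsorted numeric vector.
rank_percentile <- function(x, p) {
  n <- length(x)
  if (n == 0L) stop("percentile of empty vector")
  sort(x, method = "quick")[max(1L, ceiling(p * n))]
}

# Lower median (even n -> lower of the middle pair).
lower_median <- function(x) rank_percentile(x, 0.5)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Write a data.frame as a plain TSV with a fixed, documented column order.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
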