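# Per-run quality statistics equivalent to the four FastQC modules used for
# repository-scale QC: Basic Statistics, Sequence Length Distribution,
# Per Base Sequence Quality, Per Base N Content, plus the Duplicate
# Sequences total. All statistics stream: a run is folded chunk by chunk
# into an accumulator, so memory is bounded by read length, not run size.
#
# Conventions (see also utils.R): per-position quartiles use the lower
# nearest-rank rule; run-level mean accuracy is the unweighted mean of the
# per-position means, and median accuracy the lower median of the
# per-position medians. Both follow from the fact that the reference QC
# report exposes only per-position rows, not raw base calls.

MAX_PHRED <- 93L

#' Duplication estimator configuration
#'
#' Controls the sequence-duplication estimate. Keys are read sequences,
#' truncated to the first `truncate_to` bases when a read is longer than
#' `truncate_above` (FastQC v0.11 behaviour: >75 bp reads keyed on their
#' first 50 bases, so long-read chemistry does not defeat exact matching).
#' `"exact"` mode tallies every distinct key; `"capped"` mode tracks only the
#' first `track_limit` distinct keys and corrects the totals for unseen keys
#' with the occupancy correction described in [duplication_pct()].
#'
#' @param track_limit maximum number of distinct keys tracked in capped mode.
#' @param truncate_above reads longer than this are truncated for keying.
#' @param truncate_to truncation length.
#' @param mode `"capped"` or `"exact"`.
#' @return a `duplication_config` list.
#' @export
duplication_config <- function(track_limit = 100000L, truncate_above = 75L,
                               truncate_to = 50L,
                               mode = c("capped", "exact")) {
  mode <- match.arg(mode)
  track_limit <- as.integer(track_limit)
  stopifnot(track_limit >= 1L, truncate_to <= truncate_above)
  structure(list(track_limit = track_limit,
                 truncate_above = as.integer(truncate_above),
                 truncate_to = as.integer(truncate_to),
                 mode = mode),
            class = "duplication_config")
}

#' Basic read statistics
#'
#' @param reads a `fastq_reads` object (an empty one is allowed).
#' @return list with `total_reads`, `total_bases` and `pct_gc`. GC percent is
#'   computed over called bases only: N and non-ACGT IUPAC letters are
#'   excluded from both numerator and denominator, so `pct_gc + pct_at = 100`.
#'   An empty denominator yields 0.
#' @export
basic_stats <- function(reads) {
  acc <- qc_accumulator()
  acc$update(reads)
  list(total_reads = acc$total_reads,
       total_bases = acc$total_bases,
       pct_gc = if (acc$called_bases > 0) 100 * acc$gc_bases / acc$called_bases
                else 0)
}

#' Mean and median read length from a length distribution
#'
#' Entries are exact lengths (`"36"`) or half-open display bins (`"10-14"`),
#' which contribute their midpoint `(lo + hi) / 2`. The median is the value
#' of the entry containing the `ceiling(n / 2)`-th read in ascending order
#' (the lower median).
#'
#' @param length_distribution named numeric vector: name = length or
#'   `"lo-hi"` bin, value = read count.
#' @return list with `mean_length` and `median_length`.
#' @export
length_stats <- function(length_distribution) {
  if (length(length_distribution) == 0L) stop("empty length distribution")
  nm <- names(length_distribution)
  if (is.null(nm)) nm <- as.character(length_distribution * 0 +
                                        seq_along(length_distribution))
  counts <- as.numeric(length_distribution)
  parsed <- parse_length_entries(nm)
  o <- order(parsed$value)
  value <- parsed$value[o]
  lo <- parsed$lo[o]; hi <- parsed$hi[o]
  counts <- counts[o]
  if (any(lo[-1] <= hi[-length(hi)])) stop("overlapping length bins")
  n <- sum(counts)
  if (n == 0) stop("empty length distribution")
  mean_length <- sum(value * counts) / n
  med_idx <- ceiling(n / 2)
  median_length <- value[which(cumsum(counts) >= med_idx)[1L]]
  list(mean_length = mean_length, median_length = median_length)
}

parse_length_entries <- function(nm) {
  single <- grepl("^[0-9]+$", nm)
  binned <- grepl("^[0-9]+-[0-9]+$", nm)
  if (any(!single & !binned)) {
    stop("malformed length entry: ", nm[!single & !binned][1L])
  }
  lo <- hi <- numeric(length(nm))
  lo[single] <- hi[single] <- as.numeric(nm[single])
  if (any(binned)) {
    parts <- strsplit(nm[binned], "-", fixed = TRUE)
    lo[binned] <- as.numeric(vapply(parts, `[`, "", 1L))
    hi[binned] <- as.numeric(vapply(parts, `[`, "", 2L))
    if (any(hi[binned] < lo[binned])) stop("malformed length bin (hi < lo)")
  }
  list(value = (lo + hi) / 2, lo = lo, hi = hi)
}

#' Per-position base quality profile
#'
#' For each position i, statistics over all reads of length >= i: mean,
#' median and lower/upper quartiles of the Phred score (lower nearest-rank).
#' Run-level `mean_accuracy` is the unweighted arithmetic mean of the
#' per-position means; `median_accuracy` the lower median of the
#' per-position medians. With `weighted = TRUE`, `mean_accuracy` is instead
#' the mean over all individual base calls.
#'
#' @param reads a `fastq_reads` object with at least one read.
#' @param weighted weight the run-level mean by per-position read coverage.
#' @return list with `per_position_quality` (data.frame: position, mean,
#'   median, q1, q3, n), `mean_accuracy`, `median_accuracy`.
#' @export
per_base_quality <- function(reads, weighted = FALSE) {
  if (length(reads$read_id) == 0L) stop("no reads")
  acc <- qc_accumulator()
  acc$update(reads)
  finalize_quality(acc, weighted = weighted)
}

#' Per-position N content
#'
#' @param reads a `fastq_reads` object with at least one read.
#' @return list with `per_position_n` (data.frame: position, pct_n, n) and
#'   `n_content_pct`, the unweighted mean of the per-position percentages
#'   over positions 1..max read length.
#' @export
per_base_n_content <- function(reads) {
  if (length(reads$read_id) == 0L) stop("no reads")
  acc <- qc_accumulator()
  acc$update(reads)
  finalize_ncontent(acc)
}

#' Sequence duplication percentage
#'
#' Each read is keyed on its sequence (truncated per `config`). In exact
#' mode the duplicate percentage is `100 * (T - U) / T` with `T` total reads
#' and `U` distinct keys. In capped mode only the first `track_limit`
#' distinct keys are tracked (their counts keep accumulating after the
#' tracker fills); with `countAtLimit` the number of reads observed when the
#' tracker filled, each tracked key of count `c` is up-weighted by
#' `1 / p(c)` where
#' `p(c) = 1 - prod_{i=0}^{countAtLimit-1} (T - c - i) / (T - i)`
#' is the probability a key of multiplicity `c` is seen among the first
#' `countAtLimit` reads. Corrected totals `U* = sum 1/p(c)` and
#' `T* = sum c/p(c)` give `100 * (1 - U*/T*)`. When the tracker never fills
#' the correction is exact (`p = 1`) and both modes agree. The capped
#' estimate depends on read order by construction.
#'
#' @param reads a `fastq_reads` object.
#' @param config a [duplication_config()].
#' @return duplicate percentage in `[0, 100]`; 0 for an empty input.
#' @export
duplication_pct <- function(reads, config = duplication_config()) {
  tracker <- dup_tracker(config)
  tracker$update(reads$sequence)
  tracker$result()
}

dup_key <- function(sequences, config) {
  long <- nchar(sequences) > config$truncate_above
  sequences[long] <- substr(sequences[long], 1L, config$truncate_to)
  sequences
}

# Streaming duplication tracker. Uses a hashed environment as the key store.
dup_tracker <- function(config = duplication_config()) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  n_tracked <- 0L
  total <- 0
  count_at_limit <- NA_real_
  limit <- if (config$mode == "exact") Inf else config$track_limit

  update <- function(sequences) {
    keys <- dup_key(sequences, config)
    i <- 1L
    n <- length(keys)
    # Per-read phase while the tracker can still admit new keys.
    while (i <= n && n_tracked < limit) {
      k <- keys[[i]]
      cur <- env[[k]]
      if (is.null(cur)) {
        env[[k]] <- 1
        n_tracked <<- n_tracked + 1L
        if (n_tracked == limit) count_at_limit <<- total + i
      } else {
        env[[k]] <- cur + 1
      }
      i <- i + 1L
    }
    # Vectorized phase once full: only already-tracked keys keep counting.
    if (i <= n) {
      rest <- keys[i:n]
      tab <- table(rest)
      hits <- names(tab)[!vapply(mget(names(tab), envir = env,
                                      ifnotfound = list(NULL)),
                                 is.null, TRUE)]
      for (k in hits) env[[k]] <- env[[k]] + as.numeric(tab[[k]])
    }
    total <<- total + n
    invisible(NULL)
  }

  result <- function() {
    if (total == 0) return(0)
    counts <- as.numeric(unlist(as.list(env), use.names = FALSE))
    if (config$mode == "exact" || is.na(count_at_limit)) {
      return(100 * (total - length(counts)) / total)
    }
    p <- dup_seen_probability(counts, total, count_at_limit)
    u_star <- sum(1 / p)
    t_star <- sum(counts / p)
    100 * (1 - u_star / t_star)
  }

  list(update = update, result = result)
}

# P(a key of multiplicity c appears within the first L of T reads):
# 1 - C(T-c, L) / C(T, L), computed stably via lgamma. Clamped to (0, 1].
dup_seen_probability <- function(c, t, l) {
  p <- ifelse(t - c - l < 0, 1,
              1 - exp(lgamma(t - c + 1) - lgamma(t - c - l + 1) -
                        lgamma(t + 1) + lgamma(t - l + 1)))
  pmin(pmax(p, .Machine$double.eps), 1)
}

# ---------------------------------------------------------------------------
# Streaming accumulator shared by the metric functions and compute_run_quality

qc_accumulator <- function() {
  total_reads <- 0
  total_bases <- 0
  gc_bases <- 0
  called_bases <- 0
  len_counts <- new.env(hash = TRUE, parent = emptyenv())
  qcount <- matrix(0, nrow = MAX_PHRED + 1L, ncol = 0)  # scores 0..93
  ncount <- numeric(0)   # N calls per position
  cover <- numeric(0)    # reads covering each position

  grow <- function(l) {
    if (l > ncol(qcount)) {
      qcount <<- cbind(qcount,
                       matrix(0, nrow = MAX_PHRED + 1L,
                              ncol = l - ncol(qcount)))
      ncount <<- c(ncount, numeric(l - length(ncount)))
      cover <<- c(cover, numeric(l - length(cover)))
    }
  }

  update <- function(reads) {
    n <- length(reads$read_id)
    if (n == 0L) return(invisible(NULL))
    lens <- nchar(reads$sequence)
    total_reads <<- total_reads + n
    total_bases <<- total_bases + sum(lens)
    gc_bases <<- gc_bases +
      sum(nchar(gsub("[^GC]", "", reads$sequence, perl = TRUE)))
    called_bases <<- called_bases +
      sum(nchar(gsub("[^ACGT]", "", reads$sequence, perl = TRUE)))
    for (l in unique(lens)) {
      k <- as.character(l)
      len_counts[[k]] <- (len_counts[[k]] %||% 0) + sum(lens == l)
    }
    maxl <- max(lens)
    if (maxl == 0L) return(invisible(NULL))
    grow(maxl)
    # coverage: reads of length >= i cover position i
    cover_add <- rev(cumsum(rev(tabulate(lens, nbins = maxl))))
    cover[1:maxl] <<- cover[1:maxl] + cover_add
    # per-position quality tally via a single combined-index tabulation
    q <- unlist(reads$qualities, use.names = FALSE)
    if (length(q)) {
      if (max(q) > MAX_PHRED) stop("Phred score above ", MAX_PHRED)
      pos <- sequence(lens)
      code <- q * maxl + pos  # in 1 .. (MAX_PHRED+1)*maxl
      tab <- tabulate(code, nbins = (MAX_PHRED + 1L) * maxl)
      qcount[, 1:maxl] <<- qcount[, 1:maxl] +
        matrix(tab, nrow = maxl, ncol = MAX_PHRED + 1L)[, , drop = FALSE] |> t()
    }
    # per-position N tally
    nn <- gregexpr("N", reads$sequence, fixed = TRUE)
    npos <- unlist(nn, use.names = FALSE)
    npos <- npos[npos > 0L]
    if (length(npos)) {
      ntab <- tabulate(npos, nbins = maxl)
      ncount[1:maxl] <<- ncount[1:maxl] + ntab
    }
    invisible(NULL)
  }

  environment()
}

length_distribution_of <- function(acc) {
  lens <- as.integer(ls(acc$len_counts))
  o <- order(lens)
  counts <- vapply(as.character(lens[o]), function(k) acc$len_counts[[k]], 0)
  names(counts) <- as.character(lens[o])
  counts
}

finalize_quality <- function(acc, weighted = FALSE) {
  maxl <- ncol(acc$qcount)
  if (maxl == 0L) stop("no reads")
  pos_mean <- numeric(maxl); pos_med <- numeric(maxl)
  pos_q1 <- numeric(maxl); pos_q3 <- numeric(maxl)
  scores <- 0:MAX_PHRED
  n_i <- colSums(acc$qcount)
  for (i in seq_len(maxl)) {
    cnt <- acc$qcount[, i]
    n <- n_i[i]
    pos_mean[i] <- sum(scores * cnt) / n
    cs <- cumsum(cnt)
    pos_med[i] <- scores[which(cs >= ceiling(0.5 * n))[1L]]
    pos_q1[i] <- scores[which(cs >= max(1, ceiling(0.25 * n)))[1L]]
    pos_q3[i] <- scores[which(cs >= ceiling(0.75 * n))[1L]]
  }
  mean_acc <- if (weighted) sum(pos_mean * n_i) / sum(n_i) else mean(pos_mean)
  list(per_position_quality = data.frame(position = seq_len(maxl),
                                         mean = pos_mean, median = pos_med,
                                         q1 = pos_q1, q3 = pos_q3,
                                         n = as.numeric(n_i)),
       mean_accuracy = mean_acc,
       median_accuracy = lower_median(pos_med))
}

finalize_ncontent <- function(acc) {
  maxl <- length(acc$cover)
  if (maxl == 0L || acc$total_reads == 0) stop("no reads")
  pct <- 100 * acc$ncount / acc$cover
  list(per_position_n = data.frame(position = seq_len(maxl), pct_n = pct,
                                   n = acc$cover),
       n_content_pct = mean(pct))
}

# ---------------------------------------------------------------------------

new_run_quality <- function(run_id, total_reads, total_bases, pct_gc,
                            length_distribution, mean_length, median_length,
                            per_position_quality, mean_accuracy,
                            median_accuracy, duplicate_pct, per_position_n,
                            n_content_pct, n_files = 1L) {
  structure(list(run_id = run_id, total_reads = total_reads,
                 total_bases = total_bases, pct_gc = pct_gc,
                 length_distribution = length_distribution,
                 mean_length = mean_length, median_length = median_length,
                 per_position_quality = per_position_quality,
                 mean_accuracy = mean_accuracy,
                 median_accuracy = median_accuracy,
                 duplicate_pct = duplicate_pct,
                 per_position_n = per_position_n,
                 n_content_pct = n_content_pct,
                 n_files = n_files),
            class = "run_quality")
}

#' @export
print.run_quality <- function(x, ...) {
  cat("<run_quality> ", x$run_id, "\n",
      "  reads: ", format(x$total_reads, big.mark = ","),
      "  bases: ", format(x$total_bases, big.mark = ","), "\n",
      "  %GC: ", round(x$pct_gc, 2),
      "  dup%: ", round(x$duplicate_pct, 2),
      "  N%: ", round(x$n_content_pct, 3), "\n",
      "  length mean/median: ", round(x$mean_length, 2), "/",
      x$median_length, "\n",
      "  accuracy mean/median (Phred): ", round(x$mean_accuracy, 2), "/",
      x$median_accuracy, "\n", sep = "")
  invisible(x)
}

#' Compute the full quality record of a sequencing run
#'
#' Streams one FASTQ file, or a `_1`/`_2` paired-end file pair, and returns
#' the per-run quality record: read/base totals, GC percent, length
#' distribution with mean/median, per-position quality profile with run-level
#' mean/median base call accuracy (Phred), duplication percentage and
#' per-position/overall N content. For a pair, each mate is measured
#' independently and the two records merged: read and base totals summed,
#' every other value averaged (length-distribution counts are summed and the
#' per-position tables averaged position-wise over covering mates).
#'
#' @param run_id run identifier attached to the record and to error messages.
#' @param fastq_paths one path, or two paths forming a paired-end run.
#' @param duplication a [duplication_config()].
#' @param encoding `"auto"` or an integer ASCII offset.
#' @param weighted use the per-call weighted run-level mean accuracy instead
#'   of the default unweighted mean over positions.
#' @param chunk_size records per streamed chunk (memory/speed knob; the
#'   result is independent of it).
#' @return a `run_quality` object.
#' @export
compute_run_quality <- function(run_id, fastq_paths,
                                duplication = duplication_config(),
                                encoding = "auto", weighted = FALSE,
                                chunk_size = 5000L) {
  if (!length(fastq_paths) %in% c(1L, 2L)) {
    stop("run '", run_id, "': expected one FASTQ path or a _1/_2 pair")
  }
  parts <- lapply(fastq_paths, function(p) {
    tryCatch(run_quality_of_file(run_id, p, duplication, encoding, weighted,
                                 chunk_size),
             error = function(e) {
               stop("run '", run_id, "' (", p, "): ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  if (length(parts) == 1L) parts[[1L]] else merge_paired(parts[[1L]],
                                                         parts[[2L]])
}

run_quality_of_file <- function(run_id, path, duplication, encoding,
                                weighted, chunk_size = 5000L) {
  acc <- qc_accumulator()
  tracker <- dup_tracker(duplication)
  fastq_apply(path, function(reads) {
    acc$update(reads)
    tracker$update(reads$sequence)
  }, encoding = encoding, chunk_size = chunk_size)
  if (acc$total_reads == 0) {
    return(new_run_quality(run_id, 0, 0, 0, stats::setNames(numeric(0),
                                                            character(0)),
                           0, 0,
                           data.frame(position = integer(), mean = numeric(),
                                      median = numeric(), q1 = numeric(),
                                      q3 = numeric(), n = numeric()),
                           NA_real_, NA_real_, 0,
                           data.frame(position = integer(), pct_n = numeric(),
                                      n = numeric()),
                           0))
  }
  ld <- length_distribution_of(acc)
  ls_ <- length_stats(ld)
  qual <- finalize_quality(acc, weighted = weighted)
  ncont <- finalize_ncontent(acc)
  new_run_quality(run_id,
                  total_reads = acc$total_reads,
                  total_bases = acc$total_bases,
                  pct_gc = if (acc$called_bases > 0)
                             100 * acc$gc_bases / acc$called_bases else 0,
                  length_distribution = ld,
                  mean_length = ls_$mean_length,
                  median_length = ls_$median_length,
                  per_position_quality = qual$per_position_quality,
                  mean_accuracy = qual$mean_accuracy,
                  median_accuracy = qual$median_accuracy,
                  duplicate_pct = tracker$result(),
                  per_position_n = ncont$per_position_n,
                  n_content_pct = ncont$n_content_pct)
}

# Paired-end merge: totals added, scalar metrics averaged, length counts
# summed, per-position tables averaged over the mates covering a position.
merge_paired <- function(a, b) {
  sum_dist <- function(x, y) {
    keys <- sort(unique(as.integer(c(names(x), names(y)))))
    out <- vapply(as.character(keys),
                  function(k) (x[k] %|na|% 0) + (y[k] %|na|% 0), 0)
    names(out) <- as.character(keys)
    out
  }
  avg <- function(x, y) mean(c(x, y))
  new_run_quality(a$run_id,
                  total_reads = a$total_reads + b$total_reads,
                  total_bases = a$total_bases + b$total_bases,
                  pct_gc = avg(a$pct_gc, b$pct_gc),
                  length_distribution = sum_dist(a$length_distribution,
                                                 b$length_distribution),
                  mean_length = avg(a$mean_length, b$mean_length),
                  median_length = avg(a$median_length, b$median_length),
                  per_position_quality =
                    merge_position_tables(a$per_position_quality,
                                          b$per_position_quality),
                  mean_accuracy = avg(a$mean_accuracy, b$mean_accuracy),
                  median_accuracy = avg(a$median_accuracy, b$median_accuracy),
                  duplicate_pct = avg(a$duplicate_pct, b$duplicate_pct),
                  per_position_n = merge_position_tables(a$per_position_n,
                                                         b$per_position_n),
                  n_content_pct = avg(a$n_content_pct, b$n_content_pct),
                  n_files = a$n_files + b$n_files)
}

`%|na|%` <- function(x, default) if (is.na(x)) default else x

merge_position_tables <- function(a, b) {
  if (nrow(a) == 0L) return(b)
  if (nrow(b) == 0L) return(a)
  maxl <- max(a$position, b$position)
  cols <- setdiff(names(a), "position")
  out <- data.frame(position = seq_len(maxl))
  for (col in cols) {
    va <- rep(NA_real_, maxl); va[a$position] <- a[[col]]
    vb <- rep(NA_real_, maxl); vb[b$position] <- b[[col]]
    out[[col]] <- ifelse(is.na(va), vb, ifelse(is.na(vb), va, (va + vb) / 2))
  }
  out
}
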