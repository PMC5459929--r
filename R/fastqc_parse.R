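# Reading and writing the FastQC flat-text report format: tab-separated
# module blocks delimited by ">>Module Name<TAB>status" ... ">>END_MODULE".
# Parsing an existing report is the alternative per-run input path for data
# where the raw FASTQ is unavailable; writing one lets native records be
# checked for self-consistency through the same parser.

REQUIRED_FASTQC_MODULES <- c("Basic Statistics", "Per base sequence quality",
                             "Sequence Length Distribution",
                             "Per base N content")

split_fastqc_modules <- function(lines) {
  starts <- grep("^>>(?!END_MODULE)", lines, perl = TRUE)
  ends <- grep("^>>END_MODULE", lines)
  if (length(starts) != length(ends)) stop("unbalanced FastQC module blocks")
  blocks <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>>", "", lines[starts[i]])
    name <- strsplit(header, "\t", fixed = TRUE)[[1L]][1L]
    body <- if (ends[i] > starts[i] + 1L) {
      lines[(starts[i] + 1L):(ends[i] - 1L)]
    } else character()
    blocks[[name]] <- body
  }
  blocks
}

fastqc_table <- function(body) {
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0L) return(NULL)
  do.call(rbind, strsplit(body, "\t", fixed = TRUE))
}

# Position fields may be display bins "lo-hi"; a bin stands for one entry at
# its midpoint position.
fastqc_positions <- function(field) {
  vapply(field, function(x) {
    if (grepl("^[0-9]+-[0-9]+$", x)) {
      p <- as.numeric(strsplit(x, "-", fixed = TRUE)[[1L]])
      mean(p)
    } else {
      as.numeric(x)
    }
  }, 0, USE.NAMES = FALSE)
}

#' Parse a FastQC `fastqc_data.txt` report into a run-quality record
#'
#' Extracts the eight run-level metrics from the report's module blocks:
#' total reads and %GC from Basic Statistics, mean/median length from the
#' Sequence Length Distribution block (bins allowed, contributing midpoints),
#' mean/median base call accuracy from the Per Base Sequence Quality block's
#' Mean and Median columns (unweighted mean over positions; lower median),
#' N content as the mean of the Per Base N Content values, and the total
#' duplicate percentage from the `#Total Duplicate Percentage` line (FastQC
#' v0.11) or the `#Total Duplication Percentage` variant.
#'
#' @param text report content as a single string or character vector of lines.
#' @param run_id identifier attached to the returned record.
#' @return a `run_quality` object. Per-position tables carry binned rows at
#'   their midpoint positions.
#' @export
parse_fastqc_data <- function(text, run_id) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  if (!any(grepl("^##FastQC", lines))) {
    warning("no FastQC version banner found; attempting to parse anyway")
  }
  blocks <- split_fastqc_modules(lines)
  for (m in REQUIRED_FASTQC_MODULES) {
    if (is.null(blocks[[m]])) stop("missing module: ", m)
  }

  basic <- fastqc_table(blocks[["Basic Statistics"]])
  bget <- function(key) {
    row <- basic[basic[, 1L] == key, , drop = FALSE]
    if (nrow(row) == 0L) stop("Basic Statistics lacks '", key, "'")
    row[1L, 2L]
  }
  total_reads <- as.numeric(bget("Total Sequences"))
  pct_gc <- as.numeric(bget("%GC"))

  ldt <- fastqc_table(blocks[["Sequence Length Distribution"]])
  ld <- stats::setNames(as.numeric(ldt[, 2L]), ldt[, 1L])
  ls_ <- length_stats(ld)
  total_bases <- sum(parse_length_entries(names(ld))$value * ld)

  qt <- fastqc_table(blocks[["Per base sequence quality"]])
  qpos <- fastqc_positions(qt[, 1L])
  pq <- data.frame(position = qpos,
                   mean = as.numeric(qt[, 2L]),
                   median = as.numeric(qt[, 3L]),
                   q1 = as.numeric(qt[, 4L]),
                   q3 = as.numeric(qt[, 5L]),
                   n = if (ncol(qt) >= 6L) as.numeric(qt[, 6L]) else NA_real_)
  mean_accuracy <- mean(pq$mean)
  median_accuracy <- lower_median(pq$median)

  nt <- fastqc_table(blocks[["Per base N content"]])
  pn <- data.frame(position = fastqc_positions(nt[, 1L]),
                   pct_n = as.numeric(nt[, 2L]),
                   n = if (ncol(nt) >= 3L) as.numeric(nt[, 3L]) else NA_real_)
  n_content_pct <- mean(pn$pct_n)

  dup_line <- grep("^#Total Dupl\\w* Percentage\t", lines, value = TRUE)
  if (length(dup_line) == 0L) {
    if (is.null(blocks[["Sequence Duplication Levels"]])) {
      stop("missing module: Sequence Duplication Levels")
    }
    stop("no '#Total Duplicate Percentage' line in report")
  }
  duplicate_pct <- as.numeric(strsplit(dup_line[1L], "\t",
                                       fixed = TRUE)[[1L]][2L])

  new_run_quality(run_id, total_reads = total_reads,
                  total_bases = total_bases, pct_gc = pct_gc,
                  length_distribution = ld,
                  mean_length = ls_$mean_length,
                  median_length = ls_$median_length,
                  per_position_quality = pq,
                  mean_accuracy = mean_accuracy,
                  median_accuracy = median_accuracy,
                  duplicate_pct = duplicate_pct,
                  per_position_n = pn,
                  n_content_pct = n_content_pct)
}

#' Serialize a run-quality record in the FastQC report format
#'
#' Writes the module blocks a [parse_fastqc_data()] round trip needs:
#' Basic Statistics, Per base sequence quality, Per base N content,
#' Sequence Length Distribution and Sequence Duplication Levels with the
#' `#Total Duplicate Percentage` line. Native records are unbinned, so each
#' per-position row is written at its exact position.
#'
#' @param rq a `run_quality` object.
#' @return character vector of report lines.
#' @export
write_fastqc_data <- function(rq) {
  fmt <- function(x) trimws(formatC(x, format = "fg", digits = 15))
  out <- c("##FastQC\t0.11.x-compatible (readqc)",
           ">>Basic Statistics\tpass",
           "#Measure\tValue",
           paste0("Filename\t", rq$run_id),
           paste0("Total Sequences\t", fmt(rq$total_reads)),
           paste0("%GC\t", fmt(rq$pct_gc)),
           ">>END_MODULE",
           ">>Per base sequence quality\tpass",
           "#Base\tMean\tMedian\tLower Quartile\tUpper Quartile\tCount")
  pq <- rq$per_position_quality
  out <- c(out,
           paste(pq$position, fmt(pq$mean), fmt(pq$median), fmt(pq$q1),
                 fmt(pq$q3), fmt(pq$n), sep = "\t"),
           ">>END_MODULE",
           ">>Per base N content\tpass",
           "#Base\tN-Count\tCount")
  pn <- rq$per_position_n
  out <- c(out,
           paste(pn$position, fmt(pn$pct_n), fmt(pn$n), sep = "\t"),
           ">>END_MODULE",
           ">>Sequence Length Distribution\tpass",
           "#Length\tCount",
           paste(names(rq$length_distribution),
                 fmt(as.numeric(rq$length_distribution)), sep = "\t"),
           ">>END_MODULE",
           ">>Sequence Duplication Levels\tpass",
           paste0("#Total Duplicate Percentage\t", fmt(rq$duplicate_pct)),
           ">>END_MODULE")
  out
}

# --------------------------------------------------------------------------
# Flat serialization of run/experiment records (JSON-lines and TSV). The
# flat form carries the eight run-level metrics; per-position tables live in
# the full JSON form.

RUN_TSV_COLUMNS <- c("run_id", "total_reads", "total_bases", "pct_gc",
                     "mean_length", "median_length", "mean_accuracy",
                     "median_accuracy", "duplicate_pct", "n_content_pct")

#' Flatten run-quality records to a data.frame
#'
#' @param runs a `run_quality` object or list of them.
#' @return data.frame with one row per run and the documented column order:
#'   run_id, total_reads, total_bases, pct_gc, mean_length, median_length,
#'   mean_accuracy, median_accuracy, duplicate_pct, n_content_pct.
#' @export
run_quality_table <- function(runs) {
  if (inherits(runs, "run_quality")) runs <- list(runs)
  rows <- lapply(runs, function(r) {
    data.frame(run_id = r$run_id, total_reads = r$total_reads,
               total_bases = r$total_bases, pct_gc = r$pct_gc,
               mean_length = r$mean_length, median_length = r$median_length,
               mean_accuracy = r$mean_accuracy,
               median_accuracy = r$median_accuracy,
               duplicate_pct = r$duplicate_pct,
               n_content_pct = r$n_content_pct)
  })
  do.call(rbind, rows)[, RUN_TSV_COLUMNS]
}

run_quality_to_list <- function(r) {
  list(run_id = r$run_id, total_reads = r$total_reads,
       total_bases = r$total_bases, pct_gc = r$pct_gc,
       length_distribution = as.list(r$length_distribution),
       mean_length = r$mean_length, median_length = r$median_length,
       per_position_quality = r$per_position_quality,
       mean_accuracy = r$mean_accuracy, median_accuracy = r$median_accuracy,
       duplicate_pct = r$duplicate_pct,
       per_position_n = r$per_position_n,
       n_content_pct = r$n_content_pct, n_files = r$n_files)
}

#' Write run-quality records as JSON-lines
#'
#' One record per line, the canonical streamable intermediate format.
#'
#' @param runs a `run_quality` object or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_quality_json <- function(runs, path) {
  if (inherits(runs, "run_quality")) runs <- list(runs)
  lines <- vapply(runs, function(r) {
    jsonlite::toJSON(run_quality_to_list(r), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read run-quality records from JSON-lines
#'
#' @param path file written by [write_run_quality_json()].
#' @return list of `run_quality` objects.
#' @export
read_run_quality_json <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    ld <- unlist(x$length_distribution)
    new_run_quality(x$run_id, x$total_reads, x$total_bases, x$pct_gc,
                    ld %||% stats::setNames(numeric(0), character(0)),
                    x$mean_length, x$median_length,
                    as.data.frame(x$per_position_quality),
                    x$mean_accuracy %||% NA_real_,
                    x$median_accuracy %||% NA_real_,
                    x$duplicate_pct,
                    as.data.frame(x$per_position_n),
                    x$n_content_pct, x$n_files %||% 1L)
  })
}
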