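# Run-to-experiment aggregation. An SRA experiment groups one or more
# sequencing runs; to make experiments comparable, run records are
# concatenated with the Added/Average rules: read and base totals are added,
# every other metric (lengths, %GC, duplication, accuracy, N content) is the
# unweighted arithmetic mean over runs. Throughput is the experiment's
# summed base total.

EXPERIMENT_TSV_COLUMNS <- c("experiment_id", "n_runs", "total_reads",
                            "total_bases", "mean_length", "median_length",
                            "pct_gc", "duplicate_pct", "mean_accuracy",
                            "median_accuracy", "n_content_pct", "throughput")

AVERAGED_FIELDS <- c("mean_length", "median_length", "pct_gc",
                     "duplicate_pct", "mean_accuracy", "median_accuracy",
                     "n_content_pct")

#' Aggregate the runs of one experiment into an experiment-level record
#'
#' @param experiment_id experiment accession.
#' @param runs nonempty list of `run_quality` objects (or a single one) with
#'   distinct run ids.
#' @param weighted average the averaged metrics weighted by each run's read
#'   count instead of the default unweighted mean.
#' @return an `experiment_quality` object: `total_reads`/`total_bases`
#'   summed over runs, the other metrics averaged, and
#'   `throughput = total_bases`.
#' @export
aggregate_experiment <- function(experiment_id, runs, weighted = FALSE) {
  if (inherits(runs, "run_quality")) runs <- list(runs)
  if (length(runs) == 0L) stop("no runs for experiment ", experiment_id)
  ids <- vapply(runs, `[[`, "", "run_id")
  if (anyDuplicated(ids)) {
    stop("duplicate run_id in experiment ", experiment_id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tab <- run_quality_table(runs)
  avg <- if (weighted) {
    w <- tab$total_reads / sum(tab$total_reads)
    function(field) sum(tab[[field]] * w)
  } else {
    function(field) mean(tab[[field]])
  }
  out <- list(experiment_id = experiment_id,
              n_runs = length(runs),
              total_reads = sum(tab$total_reads),
              total_bases = sum(tab$total_bases))
  for (f in AVERAGED_FIELDS) out[[f]] <- avg(f)
  out$throughput <- out$total_bases
  structure(out, class = "experiment_quality")
}

#' @export
print.experiment_quality <- function(x, ...) {
  cat("<experiment_quality> ", x$experiment_id, " (", x$n_runs, " run",
      if (x$n_runs != 1L) "s", ")\n",
      "  reads: ", format(x$total_reads, big.mark = ","),
      "  throughput: ", format(x$throughput, big.mark = ","), " bases\n",
      "  %GC: ", round(x$pct_gc, 2), "  dup%: ", round(x$duplicate_pct, 2),
      "  accuracy: ", round(x$mean_accuracy, 2), "/",
      round(x$median_accuracy, 2), "\n", sep = "")
  invisible(x)
}

#' Group run records into experiment records via a run-to-experiment mapping
#'
#' @param runs list of `run_quality` objects.
#' @param mapping data.frame with columns `run_id` and `experiment_id` (a
#'   two-column TSV read with [read_tsv_table()] works directly).
#' @param weighted passed to [aggregate_experiment()].
#' @return list of `experiment_quality` objects sorted by experiment id.
#' @export
group_runs <- function(runs, mapping, weighted = FALSE) {
  if (length(runs) == 0L) return(list())
  stopifnot(all(c("run_id", "experiment_id") %in% names(mapping)))
  ids <- vapply(runs, `[[`, "", "run_id")
  idx <- match(ids, mapping$run_id)
  if (anyNA(idx)) {
    stop("unmapped run_id: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  exp_of <- mapping$experiment_id[idx]
  out <- lapply(sort(unique(exp_of)), function(e) {
    aggregate_experiment(e, runs[exp_of == e], weighted = weighted)
  })
  out
}

#' Flatten experiment-quality records to a data.frame
#'
#' @param experiments an `experiment_quality` object or list of them.
#' @return data.frame with the documented column order (one row per
#'   experiment).
#' @export
experiment_quality_table <- function(experiments) {
  if (inherits(experiments, "experiment_quality")) {
    experiments <- list(experiments)
  }
  rows <- lapply(experiments, function(e) {
    as.data.frame(unclass(e), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)[, EXPERIMENT_TSV_COLUMNS]
}

#' Write experiment-quality records as JSON-lines
#'
#' @param experiments an `experiment_quality` object or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_quality_json <- function(experiments, path) {
  if (inherits(experiments, "experiment_quality")) {
    experiments <- list(experiments)
  }
  lines <- vapply(experiments, function(e) {
    jsonlite::toJSON(unclass(e), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read experiment-quality records from JSON-lines
#'
#' @param path file written by [write_experiment_quality_json()].
#' @return list of `experiment_quality` objects.
#' @export
read_experiment_quality_json <- function(path) {
  lapply(readLines(path), function(ln) {
    structure(jsonlite::fromJSON(ln), class = "experiment_quality")
  })
}
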