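# Linked-data export. Quality records are flat: one subject per run or
# experiment, one typed-literal triple per numeric metric, plus rdf:type and
# an identifier triple. The vocabulary is deliberately provisional and
# overridable: predicate names are configuration, not baked-in URIs, since
# no authoritative public term set is assumed. Turtle is written (and, for
# round trips over this package's own output, read) directly; the documents
# involved are simple enough that no triple store is required.

RDF_NUMERIC_FIELDS <- list(
  run_quality = c("total_reads", "total_bases", "pct_gc", "mean_length",
                  "median_length", "mean_accuracy", "median_accuracy",
                  "duplicate_pct", "n_content_pct"),
  experiment_quality = c("n_runs", "total_reads", "total_bases",
                         "mean_length", "median_length", "pct_gc",
                         "duplicate_pct", "mean_accuracy", "median_accuracy",
                         "n_content_pct"))

#' Vocabulary mapping for RDF export
#'
#' @param base_uri base URI under which record subjects are minted
#'   (`<base_uri><id>`).
#' @param vocab_uri namespace of the metric predicates.
#' @param predicates named character vector overriding the predicate local
#'   name of any exported field.
#' @param class_name local name of the record class.
#' @return an `rdf_mapping` list.
#' @export
rdf_mapping <- function(base_uri = "https://example.org/seqstats/",
                        vocab_uri = "https://example.org/seqstats/vocab#",
                        predicates = character(),
                        class_name = "SequenceStatisticsReport") {
  all_fields <- unique(unlist(RDF_NUMERIC_FIELDS))
  preds <- stats::setNames(all_fields, all_fields)
  preds[names(predicates)] <- predicates
  if (anyDuplicated(preds)) stop("duplicate predicate name in mapping")
  structure(list(base_uri = base_uri, vocab_uri = vocab_uri,
                 predicates = preds, class_name = class_name),
            class = "rdf_mapping")
}

turtle_escape <- function(x) gsub('"', '\\\\"', x)

#' Export quality records as Turtle RDF
#'
#' One subject per record with an `rdf:type` triple, a `dct:identifier`
#' triple, and one `xsd:double`-typed triple per set numeric field. Records
#' with a required field missing (`NA`) are skipped with a warning.
#'
#' @param records list of `run_quality` and/or `experiment_quality` objects.
#' @param mapping an [rdf_mapping()].
#' @param out output path for the Turtle document.
#' @return number of triples written, invisibly the path as attribute.
#' @export
export_rdf <- function(records, mapping = rdf_mapping(), out) {
  if (inherits(records, c("run_quality", "experiment_quality"))) {
    records <- list(records)
  }
  header <- c(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "@prefix dct: <http://purl.org/dc/terms/> .",
    paste0("@prefix sqs: <", mapping$vocab_uri, "> ."),
    "")
  body <- character()
  n_triples <- 0L
  skipped <- 0L
  for (rec in records) {
    kind <- class(rec)[1L]
    fields <- RDF_NUMERIC_FIELDS[[kind]]
    if (is.null(fields)) stop("cannot export object of class ", kind)
    id <- rec$run_id %||% rec$experiment_id
    vals <- vapply(fields, function(f) as.numeric(rec[[f]] %||% NA_real_), 0)
    if (anyNA(vals)) {
      skipped <- skipped + 1L
      next
    }
    subj <- paste0("<", mapping$base_uri, id, ">")
    lines <- c(
      paste0(subj, " rdf:type sqs:", mapping$class_name, " ;"),
      paste0('    dct:identifier "', turtle_escape(id), '" ;'),
      paste0("    sqs:", mapping$predicates[fields], ' "',
             trimws(formatC(vals, format = "fg", digits = 15)),
             '"^^xsd:double',
             c(rep(" ;", length(fields) - 1L), " .")))
    body <- c(body, lines, "")
    n_triples <- n_triples + 2L + length(fields)
  }
  if (skipped > 0L) {
    warning(skipped, " record(s) with unset fields skipped")
  }
  writeLines(c(header, body), out)
  structure(n_triples, path = out)
}

#' Read flat quality records back from an exported Turtle document
#'
#' Reads Turtle documents produced by [export_rdf()] (one flat subject per
#' record, literal objects) and reconstructs the numeric record fields.
#' This is a round-trip reader for the package's own export layout, not a
#' general Turtle parser.
#'
#' @param path Turtle file.
#' @param mapping the [rdf_mapping()] used at export time.
#' @return data.frame with one row per subject: `id` plus one column per
#'   exported field found.
#' @export
read_rdf_records <- function(path, mapping = rdf_mapping()) {
  lines <- readLines(path)
  subj_re <- paste0("^<", mapping$base_uri)
  starts <- grep(subj_re, lines)
  pred_of <- stats::setNames(names(mapping$predicates), mapping$predicates)
  rows <- lapply(starts, function(s) {
    id <- sub("^<(.*)> rdf:type.*$", "\\1", lines[s])
    id <- sub(mapping$base_uri, "", id, fixed = TRUE)
    rec <- list(id = id)
    i <- s + 1L
    while (i <= length(lines) && grepl("^    ", lines[i])) {
      ln <- lines[i]
      m <- regmatches(ln, regexec(
        '^    sqs:(\\S+) "([-0-9.eE+]+)"\\^\\^xsd:double', ln))[[1L]]
      if (length(m) == 3L) {
        field <- pred_of[m[2L]]
        if (!is.na(field)) rec[[field]] <- as.numeric(m[3L])
      }
      i <- i + 1L
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
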