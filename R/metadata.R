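# Experiment and sample metadata: parsing the SRA EXPERIMENT_SET XML and
# BioSample XML, and joining categorical metadata (library strategy and
# source, instrument, organism, date) to experiment-level quality records
# through the ExperimentID <-> BioSampleID relation. Submitter metadata is
# propagated as-is: curation is out of scope and unmatched records are data,
# not errors.

#' Default platform-to-manufacturer mapping
#'
#' Maps the SRA PLATFORM child element name to a manufacturer label, the
#' facet used when summaries are split by sequencing chemistry. The mapping
#' is data, not code: pass an edited copy to [parse_sra_experiment_xml()] to
#' override it. Unlisted platforms map to `"Unknown"`.
#'
#' @return named character vector, names = SRA platform element names.
#' @export
default_manufacturer_map <- function() {
  c(ILLUMINA = "Illumina", LS454 = "454", ABI_SOLID = "SOLiD",
    PACBIO_SMRT = "PacBio", ION_TORRENT = "IonTorrent",
    OXFORD_NANOPORE = "OxfordNanopore", COMPLETE_GENOMICS = "CompleteGenomics",
    CAPILLARY = "Capillary", HELICOS = "Helicos", BGISEQ = "BGI",
    DNBSEQ = "BGI")
}

METADATA_COLUMNS <- c("experiment_id", "biosample_id", "library_strategy",
                      "library_source", "platform", "manufacturer",
                      "instrument_model", "taxonomy_id", "scientific_name",
                      "date")

empty_metadata <- function() {
  data.frame(experiment_id = character(), biosample_id = character(),
             library_strategy = character(), library_source = character(),
             platform = character(), manufacturer = character(),
             instrument_model = character(), taxonomy_id = integer(),
             scientific_name = character(), date = character(),
             stringsAsFactors = FALSE)
}

# xpath matching on the local element name, so namespace prefixes never matter
local_xpath <- function(axis, name) {
  paste0(axis, "*[local-name()='", name, "']")
}

xml_text_or_na <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

#' Parse SRA experiment metadata XML
#'
#' Extracts one record per `EXPERIMENT` element: accession, library strategy
#' and source, platform (the name of the PLATFORM child element, e.g.
#' `ILLUMINA`), instrument model, the linked BioSample accession when an
#' `EXTERNAL_ID namespace="BioSample"` is present, and any `published`/
#' `submission_date` style date attribute. Namespace prefixes are ignored
#' and element order is irrelevant. Experiments without an accession are
#' skipped with a warning.
#'
#' @param document XML text, a file path, or an `xml_document`.
#' @param manufacturer_map platform-to-manufacturer mapping
#'   (default [default_manufacturer_map()]).
#' @return data.frame with columns experiment_id, biosample_id,
#'   library_strategy, library_source, platform, manufacturer,
#'   instrument_model, taxonomy_id, scientific_name, date. Missing fields
#'   are `NA`, never fabricated; taxonomy and organism columns are left for
#'   the BioSample join.
#' @export
parse_sra_experiment_xml <- function(document,
                                     manufacturer_map =
                                       default_manufacturer_map()) {
  doc <- as_xml_doc(document)
  xml2::xml_ns_strip(doc)
  exps <- xml2::xml_find_all(doc, local_xpath("//", "EXPERIMENT"))
  if (length(exps) == 0L) return(empty_metadata())
  rows <- lapply(exps, function(e) {
    acc <- xml2::xml_attr(e, "accession")
    if (is.na(acc) || !nzchar(acc)) {
      acc <- xml_text_or_na(e, local_xpath(".//", "PRIMARY_ID"))
    }
    if (is.na(acc) || !nzchar(acc)) return(NULL)
    platform_node <- xml2::xml_find_first(e, paste0(local_xpath(".//", "PLATFORM"), "/*"))
    platform <- if (inherits(platform_node, "xml_missing")) NA_character_
                else xml2::xml_name(platform_node)
    data.frame(
      experiment_id = acc,
      biosample_id = xml_text_or_na(
        e, paste0(local_xpath(".//", "EXTERNAL_ID"),
                  "[@namespace='BioSample']")),
      library_strategy = xml_text_or_na(e, local_xpath(".//", "LIBRARY_STRATEGY")),
      library_source = xml_text_or_na(e, local_xpath(".//", "LIBRARY_SOURCE")),
      platform = platform,
      manufacturer = manufacturer_of(platform, manufacturer_map),
      instrument_model = xml_text_or_na(e, local_xpath(".//", "INSTRUMENT_MODEL")),
      taxonomy_id = NA_integer_,
      scientific_name = NA_character_,
      date = xml2::xml_attr(e, "published") %|na|%
        xml2::xml_attr(e, "submission_date"),
      stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped > 0L) {
    warning(skipped, " EXPERIMENT element(s) without accession skipped")
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty_metadata())
  do.call(rbind, rows)
}

manufacturer_of <- function(platform, map = default_manufacturer_map()) {
  out <- unname(map[platform])
  out[is.na(platform)] <- NA_character_
  out[!is.na(platform) & is.na(out)] <- "Unknown"
  out
}

as_xml_doc <- function(document) {
  if (inherits(document, "xml_document")) return(document)
  if (length(document) == 1L && !grepl("<", document, fixed = TRUE) &&
      file.exists(document)) {
    return(xml2::read_xml(document))
  }
  xml2::read_xml(paste(document, collapse = "\n"))
}

#' Parse BioSample XML into an organism lookup table
#'
#' One row per BioSample accession with the Organism taxonomy id and
#' scientific name (from the `Organism` element's attributes or its
#' `OrganismName` child). A sample without an Organism element yields a row
#' with both fields `NA`; duplicate accessions keep the last record, with a
#' warning.
#'
#' @param document XML text, a file path, or an `xml_document`.
#' @return data.frame with columns biosample_id, taxonomy_id,
#'   scientific_name.
#' @export
parse_biosample_xml <- function(document) {
  doc <- as_xml_doc(document)
  xml2::xml_ns_strip(doc)
  samples <- xml2::xml_find_all(doc, local_xpath("//", "BioSample"))
  rows <- lapply(samples, function(s) {
    acc <- xml2::xml_attr(s, "accession")
    org <- xml2::xml_find_first(s, local_xpath(".//", "Organism"))
    tax <- NA_integer_
    nm <- NA_character_
    if (!inherits(org, "xml_missing")) {
      tax_attr <- xml2::xml_attr(org, "taxonomy_id")
      tax <- if (is.na(tax_attr)) NA_integer_ else as.integer(tax_attr)
      nm <- xml2::xml_attr(org, "taxonomy_name") %|na|%
        xml_text_or_na(org, local_xpath("./", "OrganismName"))
    }
    data.frame(biosample_id = acc, taxonomy_id = tax, scientific_name = nm,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(biosample_id = character(), taxonomy_id = integer(),
               scientific_name = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(out$biosample_id)) {
    warning("duplicate BioSample accession(s): last record wins")
    out <- out[!duplicated(out$biosample_id, fromLast = TRUE), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read flat tabular metadata
#'
#' Accepts experiment metadata as a TSV with the same column names the XML
#' parsers produce, so corpus summaries can be driven without XML fixtures.
#' Missing columns are added as `NA`; a missing `manufacturer` column is
#' derived from `platform` when present.
#'
#' @param path TSV path.
#' @param manufacturer_map passed to [manufacturer_of()].
#' @return metadata data.frame with the standard columns.
#' @export
read_metadata_tsv <- function(path,
                              manufacturer_map = default_manufacturer_map()) {
  df <- read_tsv(path)
  if (!"experiment_id" %in% names(df)) {
    stop("metadata TSV lacks an experiment_id column")
  }
  if (!"manufacturer" %in% names(df) && "platform" %in% names(df)) {
    df$manufacturer <- manufacturer_of(df$platform, manufacturer_map)
  }
  for (col in METADATA_COLUMNS) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df[, METADATA_COLUMNS]
}

#' Join quality records with experiment and sample metadata
#'
#' Left join: every quality record is retained exactly once; experiment
#' metadata attaches on `experiment_id`, then organism metadata on the
#' experiment's `biosample_id`. Quality records without metadata keep `NA`
#' categories. Join statistics (matched/unmatched counts and metadata rows
#' without a quality record) are attached as the `"join_stats"` attribute.
#'
#' @param quality list of `experiment_quality` objects or a data.frame from
#'   [experiment_quality_table()].
#' @param experiments metadata data.frame (from [parse_sra_experiment_xml()]
#'   or [read_metadata_tsv()]); may be `NULL` or empty.
#' @param samples BioSample lookup from [parse_biosample_xml()]; optional.
#' @return joined data.frame, one row per quality record, quality columns
#'   first then metadata columns.
#' @export
join_records <- function(quality, experiments = NULL, samples = NULL) {
  qtab <- if (is.data.frame(quality)) quality else
    experiment_quality_table(quality)
  meta <- if (is.null(experiments) || nrow(experiments) == 0L) {
    empty_metadata()
  } else {
    experiments
  }
  idx <- match(qtab$experiment_id, meta$experiment_id)
  mcols <- setdiff(METADATA_COLUMNS, "experiment_id")
  out <- qtab
  for (col in mcols) {
    out[[col]] <- if (col %in% names(meta)) meta[[col]][idx] else NA
  }
  # organism attaches through the experiment's BioSample link; sample-table
  # fields win over anything carried in the experiment metadata
  if (!is.null(samples) && nrow(samples) > 0L) {
    sidx <- match(out$biosample_id, samples$biosample_id)
    hit <- !is.na(sidx)
    out$taxonomy_id[hit] <- samples$taxonomy_id[sidx[hit]]
    out$scientific_name[hit] <- samples$scientific_name[sidx[hit]]
  }
  stats <- list(
    n_quality = nrow(qtab),
    n_matched_experiment = sum(!is.na(idx)),
    n_unmatched_experiment = sum(is.na(idx)),
    n_metadata_unused = sum(!meta$experiment_id %in% qtab$experiment_id),
    n_matched_sample = if (is.null(samples)) 0L else
      sum(!is.na(out$biosample_id) & out$biosample_id %in%
            samples$biosample_id))
  attr(out, "join_stats") <- stats
  out
}
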