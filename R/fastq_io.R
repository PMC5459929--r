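# FASTQ input/output for the strict 4-line dialect (the form emitted by
# `fastq-dump --split-3`). Files may be plain text or gzip; `gzfile()`
# dispatches on the magic bytes, not the file extension. Wrapped (multi-line)
# FASTQ is rejected: a record whose quality string length differs from its
# sequence length is an error, never silently re-joined.

#' Detect the Phred quality encoding of FASTQ quality strings
#'
#' Scans quality lines for characters that pin down the ASCII offset:
#' any character below ASCII 59 can only occur under Phred+33; failing that,
#' any character above ASCII 74 indicates Phred+64. Ambiguous input (all
#' characters in the overlap range) defaults to Phred+33, the only encoding
#' emitted by post-2011 Illumina pipelines.
#'
#' @param quality_lines character vector of raw quality strings.
#' @param sample_limit maximum number of lines to scan (default 1000).
#' @return integer ASCII offset, `33L` or `64L`.
#' @examples
#' detect_quality_encoding("!IIII")  # 33
#' detect_quality_encoding("hhhh")   # 64
#' @export
detect_quality_encoding <- function(quality_lines, sample_limit = 1000L) {
  quality_lines <- quality_lines[nzchar(quality_lines)]
  if (length(quality_lines) == 0L) stop("no quality data")
  quality_lines <- utils::head(quality_lines, sample_limit)
  codes <- utf8ToInt(paste(quality_lines, collapse = ""))
  if (any(codes < 59L)) return(33L)
  if (any(codes > 74L)) return(64L)
  33L
}

# Decode one quality string into integer Phred scores.
decode_qualities <- function(qual, offset) {
  utf8ToInt(qual) - as.integer(offset)
}

encode_qualities <- function(scores, offset = 33L) {
  intToUtf8(as.integer(scores) + as.integer(offset))
}

# Open a path as a text connection, transparent to gzip compression.
open_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gzfile(path, open = "rt")
}

new_fastq_reads <- function(read_id, sequence, qualities) {
  structure(list(read_id = read_id, sequence = sequence,
                 qualities = qualities),
            class = "fastq_reads")
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat("<fastq_reads> ", length(x$read_id), " records, ",
      sum(nchar(x$sequence)), " bases\n", sep = "")
  invisible(x)
}

#' @export
length.fastq_reads <- function(x) length(x$read_id)

# Parse a character vector holding a whole number of 4-line FASTQ records.
# `line0` is the file line number preceding lines[1], for error reporting.
parse_fastq_lines <- function(lines, offset, line0 = 0L) {
  n <- length(lines)
  if (n %% 4L != 0L) stop("truncated FASTQ")
  if (n == 0L) {
    return(new_fastq_reads(character(), character(), list()))
  }
  heads <- lines[seq(1L, n, by = 4L)]
  seqs  <- lines[seq(2L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  if (any(!startsWith(heads, "@"))) {
    bad <- which(!startsWith(heads, "@"))[1L]
    stop("malformed FASTQ header at line ", line0 + (bad - 1L) * 4L + 1L,
         ": ", heads[bad])
  }
  ids <- sub("^@", "", sub("[ \t].*$", "", heads))
  seqs <- toupper(seqs)
  mismatch <- nchar(seqs) != nchar(quals)
  if (any(mismatch)) {
    bad <- which(mismatch)[1L]
    stop("quality length differs from sequence length for read '",
         ids[bad], "' at line ", line0 + (bad - 1L) * 4L + 4L)
  }
  off <- as.integer(offset)
  qlist <- lapply(quals, function(q) utf8ToInt(q) - off)
  if (any(unlist(lapply(qlist, function(q) length(q) && min(q) < 0L)))) {
    stop("negative Phred score after decoding; wrong encoding offset?")
  }
  new_fastq_reads(ids, seqs, qlist)
}

#' Stream a FASTQ file in chunks
#'
#' Reads `path` (plain or gzip) in chunks of `chunk_size` records and calls
#' `fun(reads)` on each chunk, a `fastq_reads` object. This is the streaming
#' backbone of [compute_run_quality()]: per-run metrics are accumulated chunk
#' by chunk so arbitrarily large runs never need to fit in memory.
#'
#' @param path FASTQ file path.
#' @param fun function of one `fastq_reads` argument, called per chunk.
#' @param encoding `"auto"` (detect from the first chunk) or an integer offset.
#' @param chunk_size records per chunk.
#' @return number of records processed, invisibly.
#' @export
fastq_apply <- function(path, fun, encoding = "auto", chunk_size = 5000L) {
  con <- open_text(path)
  on.exit(close(con))
  offset <- if (identical(encoding, "auto")) NULL else as.integer(encoding)
  total <- 0L
  line0 <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size * 4L)
    if (length(lines) == 0L) break
    if (is.null(offset)) {
      n4 <- (length(lines) %/% 4L) * 4L
      if (n4 == 0L) stop("truncated FASTQ")
      offset <- detect_quality_encoding(lines[seq(4L, n4, by = 4L)])
    }
    reads <- parse_fastq_lines(lines, offset, line0)
    fun(reads)
    total <- total + length(reads)
    line0 <- line0 + length(lines)
  }
  invisible(total)
}

#' Read a whole FASTQ file into memory
#'
#' @inheritParams fastq_apply
#' @return a `fastq_reads` object: parallel `read_id`, `sequence` vectors and
#'   a `qualities` list of integer Phred scores.
#' @export
read_fastq <- function(path, encoding = "auto") {
  chunks <- list()
  fastq_apply(path, function(r) chunks[[length(chunks) + 1L]] <<- r,
              encoding = encoding)
  if (length(chunks) == 0L) {
    return(new_fastq_reads(character(), character(), list()))
  }
  new_fastq_reads(
    unlist(lapply(chunks, `[[`, "read_id")),
    unlist(lapply(chunks, `[[`, "sequence")),
    do.call(c, lapply(chunks, `[[`, "qualities"))
  )
}

#' Write reads as 4-line FASTQ
#'
#' @param reads a `fastq_reads` object.
#' @param path output path; written gzip-compressed when `gzip = TRUE`.
#' @param gzip compress the output.
#' @param offset ASCII offset used to encode quality scores.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, gzip = FALSE, offset = 33L) {
  n <- length(reads$read_id)
  con <- if (gzip) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con))
  if (n > 0L) {
    quals <- vapply(reads$qualities, encode_qualities, "", offset = offset)
    lines <- character(4L * n)
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$read_id)
    lines[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- quals
    writeLines(lines, con)
  }
  invisible(path)
}

#' Re-encode a FASTQ file under a different quality offset
#'
#' Utility for producing Phred+64 test inputs from the generator's Phred+33
#' output. Scores that cannot be represented under the target offset raise
#' an error rather than being clamped.
#'
#' @param in_path input FASTQ (plain or gzip).
#' @param out_path output path.
#' @param offset target ASCII offset (default 64).
#' @return `out_path`, invisibly.
#' @export
reencode_fastq <- function(in_path, out_path, offset = 64L) {
  reads <- read_fastq(in_path)
  if (length(reads$qualities) &&
      max(unlist(reads$qualities), 0L) + offset > 126L) {
    stop("quality score not representable under offset ", offset)
  }
  write_fastq(reads, out_path, gzip = grepl("\\.gz$", out_path),
              offset = offset)
}
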