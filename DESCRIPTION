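Package: readqc
Title: Sequencing Run Quality Metrics and Repository-Scale QC Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes FastQC-equivalent quality statistics for sequencing runs
    directly from FASTQ files (plain or gzip): read and base totals, GC
    content, read length distributions, per-position Phred quality profiles,
    per-position N content, and sequence duplication levels with the capped
    tracker and occupancy correction used by FastQC. Per-run records are
    aggregated to SRA-experiment level (read and base totals added, all other
    metrics averaged), joined with experiment and BioSample metadata parsed
    from SRA XML or flat tables, and summarized at repository scale as
    category count tables, histograms, threshold fractions and quarterly
    box-plot tables. Includes a synthetic FASTQ and corpus generator with
    recorded ground truth, serializers for TSV, JSON-lines and Turtle RDF,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
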