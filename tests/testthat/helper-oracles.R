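# Independent brute-force oracles. These deliberately avoid the package's
# streaming accumulators: metrics are recomputed from an in-memory read set
# with plain loops and sorts, so agreement between the two routes is
# evidence, not tautology.

# lower nearest-rank percentile, restated independently
o_rank <- function(x, p) sort(x)[max(1L, ceiling(p * length(x)))]

oracle_metrics <- function(reads) {
  seqs <- reads$sequence
  quals <- reads$qualities
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  all_bases <- unlist(chars)
  called <- sum(all_bases %in% c("A", "C", "G", "T"))
  gc <- sum(all_bases %in% c("G", "C"))
  maxl <- max(lens)

  pos_scores <- lapply(seq_len(maxl), function(i) {
    unlist(lapply(quals, function(q) if (length(q) >= i) q[[i]]))
  })
  pos_mean <- vapply(pos_scores, mean, 0)
  pos_med <- vapply(pos_scores, o_rank, 0, p = 0.5)
  pos_q1 <- vapply(pos_scores, o_rank, 0, p = 0.25)
  pos_q3 <- vapply(pos_scores, o_rank, 0, p = 0.75)

  pos_n_pct <- vapply(seq_len(maxl), function(i) {
    covering <- lens >= i
    100 * sum(vapply(chars[covering], function(b) b[[i]] == "N", TRUE)) /
      sum(covering)
  }, 0)

  list(total_reads = length(seqs),
       total_bases = sum(lens),
       pct_gc = if (called > 0) 100 * gc / called else 0,
       mean_length = sum(lens) / length(seqs),
       median_length = o_rank(lens, 0.5),
       pos_mean = pos_mean, pos_med = pos_med,
       pos_q1 = pos_q1, pos_q3 = pos_q3,
       mean_accuracy = mean(pos_mean),
       median_accuracy = o_rank(pos_med, 0.5),
       pos_n_pct = pos_n_pct,
       n_content_pct = mean(pos_n_pct),
       duplicate_pct_exact = {
         keys <- ifelse(nchar(seqs) > 75, substr(seqs, 1, 50), seqs)
         100 * (length(keys) - length(unique(keys))) / length(keys)
       })
}

# small in-memory read set built by hand (no package generator involved)
make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- lapply(nchar(seqs), function(l) rep.int(30L, l))
  }
  structure(list(read_id = sprintf("r%d", seq_along(seqs)),
                 sequence = seqs, qualities = quals),
            class = "fastq_reads")
}

random_spec <- function(seed) {
  n_templ <- if (seed %% 3 == 0) 20L else NULL
  synthetic_spec(
    n_reads = sample(20:200, 1),
    length_model = if (seed %% 2 == 0) {
      stats::setNames(c(0.4, 0.4, 0.2), c(60, 80, 120))
    } else {
      sample(c(36L, 75L, 100L, 151L), 1)
    },
    gc_prob = stats::runif(1, 0.2, 0.8),
    n_prob = sample(c(0, 0.01, 0.05), 1),
    n_templates = n_templ,
    copies_per_template = if (!is.null(n_templ)) sample(1:8, 20,
                                                        replace = TRUE),
    seed = seed)
}

expect_metrics_match_oracle <- function(rq, o, tol = 1e-10) {
  expect_equal(rq$total_reads, o$total_reads)
  expect_equal(rq$total_bases, o$total_bases)
  expect_equal(rq$pct_gc, o$pct_gc, tolerance = tol)
  expect_equal(rq$mean_length, o$mean_length, tolerance = tol)
  expect_equal(rq$median_length, o$median_length)
  expect_equal(rq$per_position_quality$mean, o$pos_mean, tolerance = tol)
  expect_equal(rq$per_position_quality$median, o$pos_med)
  expect_equal(rq$per_position_quality$q1, o$pos_q1)
  expect_equal(rq$per_position_quality$q3, o$pos_q3)
  expect_equal(rq$mean_accuracy, o$mean_accuracy, tolerance = tol)
  expect_equal(rq$median_accuracy, o$median_accuracy)
  expect_equal(rq$per_position_n$pct_n, o$pos_n_pct, tolerance = tol)
  expect_equal(rq$n_content_pct, o$n_content_pct, tolerance = tol)
  expect_equal(rq$duplicate_pct, o$duplicate_pct_exact, tolerance = tol)
}

# hand-built run record with controllable metric values
fake_run <- function(id, total_reads = 100, total_bases = 10000,
                     pct_gc = 50, mean_length = 100, median_length = 100,
                     mean_accuracy = 30, median_accuracy = 32,
                     duplicate_pct = 10, n_content_pct = 0.5) {
  readqc:::new_run_quality(
    id, total_reads, total_bases, pct_gc,
    stats::setNames(total_reads, as.character(total_bases / total_reads)),
    mean_length, median_length,
    data.frame(position = 1, mean = mean_accuracy, median = median_accuracy,
               q1 = 0, q3 = 40, n = total_reads),
    mean_accuracy, median_accuracy, duplicate_pct,
    data.frame(position = 1, pct_n = n_content_pct, n = total_reads),
    n_content_pct)
}

# minimal well-formed SRA experiment XML fixture
sra_experiment_xml <- function(...) {
  exps <- paste(c(...), collapse = "\n")
  paste0("<EXPERIMENT_SET>\n", exps, "\n</EXPERIMENT_SET>")
}

experiment_node <- function(accession, strategy = "WGS",
                            source = "GENOMIC", platform = "ILLUMINA",
                            model = "Illumina HiSeq 2000",
                            biosample = NULL) {
  bs <- if (!is.null(biosample)) {
    paste0("<EXTERNAL_ID namespace=\"BioSample\">", biosample,
           "</EXTERNAL_ID>")
  } else ""
  strat <- if (!is.na(strategy)) {
    paste0("<LIBRARY_STRATEGY>", strategy, "</LIBRARY_STRATEGY>")
  } else ""
  paste0("<EXPERIMENT accession=\"", accession, "\">",
         "<IDENTIFIERS><PRIMARY_ID>", accession, "</PRIMARY_ID>", bs,
         "</IDENTIFIERS>",
         "<DESIGN><LIBRARY_DESCRIPTOR>", strat,
         "<LIBRARY_SOURCE>", source, "</LIBRARY_SOURCE>",
         "</LIBRARY_DESCRIPTOR></DESIGN>",
         "<PLATFORM><", platform, "><INSTRUMENT_MODEL>", model,
         "</INSTRUMENT_MODEL></", platform, "></PLATFORM>",
         "</EXPERIMENT>")
}

biosample_xml <- function(entries) {
  body <- vapply(seq_len(nrow(entries)), function(i) {
    org <- if (!is.na(entries$taxonomy_id[i])) {
      paste0("<Organism taxonomy_id=\"", entries$taxonomy_id[i],
             "\" taxonomy_name=\"", entries$scientific_name[i],
             "\"/>")
    } else ""
    paste0("<BioSample accession=\"", entries$biosample_id[i],
           "\"><Description>", org, "</Description></BioSample>")
  }, "")
  paste0("<BioSampleSet>", paste(body, collapse = ""), "</BioSampleSet>")
}
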