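# Synthetic fixtures with recorded ground truth. The generator stands in
# for a sequencing archive: it emits FASTQ runs with controlled GC, N,
# length, quality and duplication structure, and whole corpora of
# experiment records with metadata, so that every analysis stage can be
# verified against known truth without any download. Ground truth is
# tallied from the emitted reads themselves (not from the spec's expected
# probabilities), so deterministic metrics can be asserted exactly.

#' Specification of a synthetic FASTQ run
#'
#' @param n_reads number of reads to emit.
#' @param length_model read-length model: a single fixed length, or a named
#'   numeric vector of probabilities over lengths (names = lengths).
#' @param gc_prob per-base probability of G or C (G and C equiprobable, as
#'   are A and T).
#' @param n_prob per-base probability of an N call (applied after base
#'   choice).
#' @param quality_mean mean Phred score at the first position.
#' @param quality_slope per-position decline: the mean at position i is
#'   `quality_mean - quality_slope * (i - 1)`.
#' @param quality_sd Gaussian spread around the per-position mean.
#' @param quality_clamp length-2 range scores are clamped to after rounding
#'   to integers.
#' @param n_templates if set, reads are drawn as copies of this many distinct
#'   template sequences instead of being sampled independently.
#' @param copies_per_template copies emitted per template (scalar or vector
#'   of length `n_templates`); overrides `n_reads`.
#' @param seed RNG seed making the emitted file byte-identical across runs.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_reads = 1000L, length_model = 100L,
                           gc_prob = 0.5, n_prob = 0, quality_mean = 38,
                           quality_slope = 0.1, quality_sd = 2,
                           quality_clamp = c(2L, 40L), n_templates = NULL,
                           copies_per_template = NULL, seed = 1L) {
  stopifnot(gc_prob >= 0, gc_prob <= 1, n_prob >= 0, n_prob <= 1,
            n_reads >= 0)
  structure(list(n_reads = as.integer(n_reads), length_model = length_model,
                 gc_prob = gc_prob, n_prob = n_prob,
                 quality_mean = quality_mean, quality_slope = quality_slope,
                 quality_sd = quality_sd,
                 quality_clamp = as.integer(quality_clamp),
                 n_templates = n_templates,
                 copies_per_template = copies_per_template,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

sample_lengths <- function(model, n) {
  if (is.null(names(model))) {
    if (length(model) != 1L) stop("unnamed length model must be one length")
    return(rep(as.integer(model), n))
  }
  p <- as.numeric(model) / sum(model)
  sample(as.integer(names(model)), n, replace = TRUE, prob = p)
}

random_sequence <- function(len, gc_prob, n_prob) {
  if (len == 0L) return("")
  p <- c(A = (1 - gc_prob) / 2, C = gc_prob / 2, G = gc_prob / 2,
         T = (1 - gc_prob) / 2)
  bases <- sample(names(p), len, replace = TRUE, prob = p)
  if (n_prob > 0) {
    bases[stats::runif(len) < n_prob] <- "N"
  }
  paste(bases, collapse = "")
}

random_qualities <- function(len, spec) {
  if (len == 0L) return(integer())
  mu <- spec$quality_mean - spec$quality_slope * (seq_len(len) - 1L)
  q <- round(stats::rnorm(len, mean = mu, sd = spec$quality_sd))
  pmin(pmax(q, spec$quality_clamp[1L]), spec$quality_clamp[2L])
}

#' Generate a synthetic FASTQ file with recorded ground truth
#'
#' Emits a 4-line-dialect FASTQ file (gzip when the path ends in `.gz`) and
#' returns the ground-truth metrics obtained by tallying the emitted reads
#' directly: total reads and bases, GC percent over called bases, mean read
#' length, N content as the mean of per-position N percentages, and the
#' exact duplication percentage of the emitted sequences.
#'
#' @param spec a [synthetic_spec()].
#' @param out output path.
#' @return list with `path`, `truth` (the tallied metrics) and the
#'   `synthetic_spec` used.
#' @export
generate_fastq <- function(spec, out) {
  stopifnot(inherits(spec, "synthetic_spec"))
  reads <- with_seed(spec$seed, generate_reads(spec))
  write_fastq(reads, out, gzip = grepl("\\.gz$", out))
  list(path = out, truth = tally_truth(reads), spec = spec)
}

generate_reads <- function(spec) {
  if (!is.null(spec$n_templates)) {
    copies <- spec$copies_per_template %||% 5L
    if (length(copies) == 1L) copies <- rep(copies, spec$n_templates)
    stopifnot(length(copies) == spec$n_templates)
    lens <- sample_lengths(spec$length_model, spec$n_templates)
    templates <- vapply(lens, random_sequence, "",
                        gc_prob = spec$gc_prob, n_prob = spec$n_prob)
    idx <- sample(rep.int(seq_len(spec$n_templates), copies))
    seqs <- templates[idx]
  } else {
    lens <- sample_lengths(spec$length_model, spec$n_reads)
    seqs <- vapply(lens, random_sequence, "",
                   gc_prob = spec$gc_prob, n_prob = spec$n_prob)
  }
  quals <- lapply(nchar(seqs), random_qualities, spec = spec)
  new_fastq_reads(sprintf("read_%06d", seq_along(seqs)), seqs, quals)
}

# Ground truth by direct tally of the emitted reads.
tally_truth <- function(reads) {
  n <- length(reads$read_id)
  if (n == 0L) {
    return(list(total_reads = 0, total_bases = 0, pct_gc = 0,
                mean_length = 0, n_content_pct = 0, duplicate_pct = 0))
  }
  bs <- basic_stats(reads)
  nc <- per_base_n_content(reads)
  list(total_reads = bs$total_reads, total_bases = bs$total_bases,
       pct_gc = bs$pct_gc,
       mean_length = bs$total_bases / bs$total_reads,
       n_content_pct = nc$n_content_pct,
       duplicate_pct = duplication_pct(
         reads, duplication_config(mode = "exact")))
}

#' Generate a synthetic corpus of experiment records with ground truth
#'
#' Emits experiment-level quality records with categorical metadata drawn
#' from a category mix, plus the exact summary tables the corpus summaries
#' must reproduce. Per-experiment throughput is drawn log-normally around a
#' per-category (or per-quarter) location so that faceted histograms and
#' quarterly box tables have signal; accuracy and N content are drawn from
#' ranges typical of short-read archives.
#'
#' @param n_experiments number of experiments.
#' @param category_mix named probability vector over library strategies
#'   (must sum to 1).
#' @param quarters character vector of quarter start dates (`"2014-01-01"`,
#'   ...) experiments are spread over uniformly.
#' @param quarterly_log10_throughput optional numeric vector, one value per
#'   quarter: the per-quarter mean of log10 throughput (a known ramp for
#'   time-series recovery tests). Default a flat 8.5.
#' @param seed RNG seed.
#' @return list with `joined` (the joined table), `metadata` (the metadata
#'   data.frame), and `truth`: category count table, throughput moments and
#'   per-quarter means tallied from the emitted records.
#' @export
generate_corpus <- function(n_experiments = 1000L,
                            category_mix = c(WGS = 0.35, `RNA-Seq` = 0.25,
                                             AMPLICON = 0.2,
                                             `ChIP-Seq` = 0.1, WXS = 0.1),
                            quarters = c("2014-01-01", "2014-04-01",
                                         "2014-07-01", "2014-10-01"),
                            quarterly_log10_throughput = NULL,
                            seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category mix probabilities must sum to 1")
  }
  with_seed(seed, {
    strat <- sample(names(category_mix), n_experiments, replace = TRUE,
                    prob = category_mix)
    qidx <- sample(seq_along(quarters), n_experiments, replace = TRUE)
    qmu <- quarterly_log10_throughput %||% rep(8.5, length(quarters))
    stopifnot(length(qmu) == length(quarters))
    log_tp <- stats::rnorm(n_experiments, mean = qmu[qidx], sd = 0.4)
    throughput <- round(10^log_tp)
    mean_len <- round(stats::runif(n_experiments, 75, 150))
    total_reads <- pmax(1, round(throughput / mean_len))
    date <- as.Date(quarters[qidx]) +
      sample.int(85L, n_experiments, replace = TRUE) - 1L
    src_of <- c(WGS = "GENOMIC", `RNA-Seq` = "TRANSCRIPTOMIC",
                AMPLICON = "METAGENOMIC", `ChIP-Seq` = "GENOMIC",
                WXS = "GENOMIC")
    joined <- data.frame(
      experiment_id = sprintf("SXP%06d", seq_len(n_experiments)),
      n_runs = 1L,
      total_reads = total_reads,
      total_bases = throughput,
      mean_length = as.numeric(mean_len),
      median_length = as.numeric(mean_len),
      pct_gc = stats::runif(n_experiments, 35, 65),
      duplicate_pct = stats::runif(n_experiments, 0, 40),
      mean_accuracy = stats::runif(n_experiments, 20, 40),
      median_accuracy = stats::runif(n_experiments, 22, 40),
      n_content_pct = stats::rexp(n_experiments, rate = 2),
      throughput = throughput,
      biosample_id = sprintf("SAMN%06d", seq_len(n_experiments)),
      library_strategy = strat,
      library_source = unname(src_of[strat]) %|NA|% "OTHER",
      platform = "ILLUMINA",
      manufacturer = "Illumina",
      instrument_model = "Illumina HiSeq 2000",
      taxonomy_id = 9606L,
      scientific_name = "Homo sapiens",
      date = as.character(date),
      stringsAsFactors = FALSE)
  })
  metadata <- joined[, METADATA_COLUMNS]
  truth <- list(
    category_counts = {
      tab <- table(joined$library_strategy)
      df <- data.frame(category = names(tab), count = as.numeric(tab),
                       stringsAsFactors = FALSE)
      df <- df[order(-df$count, df$category), , drop = FALSE]
      rownames(df) <- NULL
      df
    },
    throughput_mean = mean(joined$throughput),
    throughput_median = lower_median(joined$throughput),
    quarterly_mean_log10_throughput = vapply(
      sort(unique(quarter_label(joined$date))),
      function(q) mean(log10(joined$throughput[quarter_label(joined$date)
                                               == q])), 0))
  list(joined = joined, metadata = metadata, truth = truth)
}

`%|NA|%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}
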