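test_that("basic statistics count GC over called bases only", {
  r <- make_reads(c("ACGT", "GGCC"))
  s <- basic_stats(r)
  expect_equal(s$total_reads, 2)
  expect_equal(s$total_bases, 8)
  expect_equal(s$pct_gc, 75)

  # N-only read: empty GC denominator
  s2 <- basic_stats(make_reads("NNNN"))
  expect_equal(s2$pct_gc, 0)
  expect_equal(s2$total_bases, 4)

  # other IUPAC letters are neither GC nor called
  s3 <- basic_stats(make_reads("ACGTRYSW"))
  expect_equal(s3$pct_gc, 50)
  expect_equal(s3$total_bases, 8)

  # empty stream allowed
  s4 <- basic_stats(make_reads(character()))
  expect_equal(s4$total_reads, 0)
  expect_equal(s4$pct_gc, 0)
})

test_that("simulated GC fraction lands near its generating probability", {
  p <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(synthetic_spec(n_reads = 1000, length_model = 100,
                                gc_prob = 0.5, seed = 91), p)
  s <- basic_stats(read_fastq(p))
  expect_lt(abs(s$pct_gc - 50), 3)  # ~6 binomial sd at n = 1e5 bases
})

test_that("length statistics handle exact entries, bins and medians", {
  expect_equal(length_stats(c(`4` = 2)),
               list(mean_length = 4, median_length = 4))
  # bins contribute midpoints; the 2nd of 4 reads sits in the first bin
  ls_ <- length_stats(c(`10-14` = 3, `15-19` = 1))
  expect_equal(ls_$mean_length, 13.25)
  expect_equal(ls_$median_length, 12)
  # lower-median convention on even n
  expect_equal(length_stats(c(`1` = 1, `100` = 1))$median_length, 1)
  # bin oracle: expanding bins into explicit read lists agrees
  expanded <- c(rep(12, 3), rep(17, 1))
  expect_equal(ls_$mean_length, mean(expanded))
  expect_equal(ls_$median_length, o_rank(expanded, 0.5))
  expect_error(length_stats(c(`10-14` = 1, `12-16` = 1)), "overlapping")
  expect_error(length_stats(c(`x` = 1)), "malformed")
  expect_error(length_stats(numeric()), "empty")
})

test_that("per-base quality profile and run-level accuracy follow the
           per-position rules", {
  r1 <- make_reads("ACG", list(c(10L, 20L, 30L)))
  q1 <- per_base_quality(r1)
  expect_equal(q1$per_position_quality$mean, c(10, 20, 30))
  expect_equal(q1$mean_accuracy, 20)
  expect_equal(q1$median_accuracy, 20)

  r2 <- make_reads(c("AC", "GT"), list(c(0L, 0L), c(40L, 40L)))
  q2 <- per_base_quality(r2)
  expect_equal(q2$per_position_quality$mean, c(20, 20))
  expect_equal(q2$mean_accuracy, 20)

  # ragged reads: position stats are over covering reads only
  r3 <- make_reads(c("ACGT", "AC"), list(c(10L, 10L, 30L, 40L),
                                         c(20L, 30L)))
  q3 <- per_base_quality(r3)
  expect_equal(q3$per_position_quality$mean, c(15, 20, 30, 40))
  expect_equal(q3$per_position_quality$n, c(2, 2, 1, 1))
  # lower median on two covering reads
  expect_equal(q3$per_position_quality$median, c(10, 10, 30, 40))

  expect_error(per_base_quality(make_reads(character())), "no reads")
})

test_that("weighted mean accuracy weights positions by coverage", {
  r <- make_reads(c("ACGT", "AC"), list(c(10L, 10L, 30L, 40L),
                                        c(20L, 30L)))
  q <- per_base_quality(r, weighted = TRUE)
  expect_equal(q$mean_accuracy, mean(c(10, 10, 30, 40, 20, 30)))
})

test_that("simulated declining quality recovers the model expectation", {
  p <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(synthetic_spec(n_reads = 500, length_model = 100,
                                quality_mean = 38, quality_slope = 0.1,
                                quality_sd = 2, seed = 17), p)
  q <- per_base_quality(read_fastq(p))
  # expectation: mean over i of (38 - 0.1 * (i - 1)), i = 1..100
  expect_lt(abs(q$mean_accuracy - 33.05), 0.5)
})

test_that("per-position N content averages unweighted over positions", {
  n1 <- per_base_n_content(make_reads("ANNN"))
  expect_equal(n1$per_position_n$pct_n, c(0, 100, 100, 100))
  expect_equal(n1$n_content_pct, 75)

  expect_equal(per_base_n_content(make_reads(c("ACGT", "ACGT")))$
                 n_content_pct, 0)

  n3 <- per_base_n_content(make_reads(c("AN", "AA", "AA", "AA")))
  expect_equal(n3$per_position_n$pct_n, c(0, 25))
  expect_equal(n3$n_content_pct, 12.5)
  expect_error(per_base_n_content(make_reads(character())), "no reads")
})

test_that("exact duplication counts distinct sequence keys", {
  r <- make_reads(c("AAAA", "AAAA", "CCCC"))
  expect_equal(duplication_pct(r, duplication_config(mode = "exact")),
               100 / 3)
  expect_equal(duplication_pct(make_reads(character())), 0)
})

test_that("reads beyond 75 bases are keyed on their first 50", {
  long_a <- paste(rep("A", 80), collapse = "")
  long_b <- paste(c(rep("A", 50), rep("C", 30)), collapse = "")  # same key
  r <- make_reads(c(long_a, long_b))
  expect_equal(duplication_pct(r, duplication_config(mode = "exact")), 50)
  # at exactly 75 bases no truncation happens
  j75a <- paste(rep("A", 75), collapse = "")
  j75b <- paste(c(rep("A", 74), "C"), collapse = "")
  r2 <- make_reads(c(j75a, j75b))
  expect_equal(duplication_pct(r2, duplication_config(mode = "exact")), 0)
})

test_that("capped duplication equals exact mode when the tracker never
           fills", {
  set.seed(23)
  for (i in 1:10) {
    seqs <- sample(vapply(1:30, function(j) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
            collapse = "")
    }, ""), 120, replace = TRUE)
    r <- make_reads(seqs)
    expect_equal(
      duplication_pct(r, duplication_config(track_limit = 1000,
                                            mode = "capped")),
      duplication_pct(r, duplication_config(mode = "exact")))
  }
})

test_that("capped duplication with occupancy correction stays near the
           analytic value on a template pool", {
  p <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(synthetic_spec(n_templates = 200, copies_per_template = 5,
                                length_model = 60, seed = 29), p)
  reads <- read_fastq(p)
  exact <- duplication_pct(reads, duplication_config(mode = "exact"))
  expect_equal(exact, 80)  # 100 * (1 - 200/1000)
  capped <- duplication_pct(reads, duplication_config(track_limit = 50,
                                                      mode = "capped"))
  expect_lt(abs(capped - 80), 2)
})

test_that("capped-mode error stays small across duplication levels", {
  set.seed(31)
  for (lvl in c(2L, 5L, 10L)) {
    n_templ <- 300L
    copies <- sample(1:lvl, n_templ, replace = TRUE)
    p <- withr::local_tempfile(fileext = ".fastq")
    generate_fastq(synthetic_spec(n_templates = n_templ,
                                  copies_per_template = copies,
                                  length_model = 50,
                                  seed = 100L + lvl), p)
    reads <- read_fastq(p)
    exact <- duplication_pct(reads, duplication_config(mode = "exact"))
    capped <- duplication_pct(reads,
                              duplication_config(track_limit = 100,
                                                 mode = "capped"))
    expect_lt(abs(capped - exact), 5)
  }
})

test_that("run quality of a single file matches the brute-force oracle", {
  p <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(synthetic_spec(n_reads = 150,
                                length_model = c(`40` = 0.5, `60` = 0.5),
                                gc_prob = 0.6, n_prob = 0.02, seed = 3), p)
  rq <- compute_run_quality("R1", p, chunk_size = 16L)
  o <- oracle_metrics(read_fastq(p))
  expect_metrics_match_oracle(rq, o)
  expect_equal(sum(rq$length_distribution), rq$total_reads)
  expect_equal(sum(as.numeric(names(rq$length_distribution)) *
                     rq$length_distribution), rq$total_bases)
})

test_that("metrics are invariant to read order", {
  p <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(synthetic_spec(n_reads = 80, length_model = 50,
                                n_prob = 0.03, seed = 41), p)
  reads <- read_fastq(p)
  perm <- withr::with_seed(1, sample(length(reads)))
  shuffled <- make_reads(reads$sequence[perm], reads$qualities[perm])
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(shuffled, p2)
  a <- compute_run_quality("A", p)
  b <- compute_run_quality("B", p2)
  for (f in c("total_reads", "total_bases", "pct_gc", "mean_length",
              "median_length", "mean_accuracy", "median_accuracy",
              "n_content_pct", "duplicate_pct")) {
    expect_equal(a[[f]], b[[f]], info = f)
  }
})

test_that("paired-end mates are merged by sum/average rules", {
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(synthetic_spec(n_reads = 60, length_model = 40,
                                gc_prob = 0.4, seed = 51), p1)
  generate_fastq(synthetic_spec(n_reads = 60, length_model = 40,
                                gc_prob = 0.6, seed = 52), p2)
  m1 <- compute_run_quality("R_1", p1)
  m2 <- compute_run_quality("R_2", p2)
  pair <- compute_run_quality("R", c(p1, p2))
  expect_equal(pair$total_reads, m1$total_reads + m2$total_reads)
  expect_equal(pair$total_bases, m1$total_bases + m2$total_bases)
  expect_equal(pair$pct_gc, (m1$pct_gc + m2$pct_gc) / 2)
  expect_equal(pair$mean_accuracy,
               (m1$mean_accuracy + m2$mean_accuracy) / 2)
  expect_equal(pair$duplicate_pct,
               (m1$duplicate_pct + m2$duplicate_pct) / 2)
  expect_equal(sum(pair$length_distribution), pair$total_reads)

  # identical mates: averaged fields unchanged
  pair_same <- compute_run_quality("S", c(p1, p1))
  expect_equal(pair_same$mean_accuracy, m1$mean_accuracy)
  expect_equal(pair_same$total_reads, 2 * m1$total_reads)
})

test_that("I/O errors carry the run id", {
  expect_error(compute_run_quality("RX", "/nonexistent/file.fastq"), "RX")
  expect_error(compute_run_quality("RX", c("a", "b", "c")), "pair")
})
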