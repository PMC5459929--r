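test_that("percentages reproduce published repository values exactly", {
  expect_equal(percentage(426841, 1171313), 36.4)   # WGS share
  expect_equal(percentage(216896, 1171313), 18.5)   # human samples
  expect_equal(percentage(244457, 1171313), 20.9)   # metagenome samples
  expect_equal(percentage(542332, 1171313), 46.3)   # HiSeq 2000 experiments
  expect_equal(percentage(1103515, 1171313), 94.2)  # N below 1 percent
  expect_equal(percentage(0, 5), 0)
  expect_error(percentage(1, 0), "denominator")
  expect_error(percentage(6, 5), "exceeds")
})

test_that("rounding is half away from zero at one decimal", {
  expect_equal(percentage(5, 1000), 0.5)    # 0.5 stays 0.5
  expect_equal(percentage(25, 10000), 0.3)  # 0.25 -> 0.3, not banker's 0.2
  expect_equal(percentage(15, 10000), 0.2)  # 0.15 -> 0.2
})

test_that("category counts rank, collapse to other, and total correctly", {
  joined <- data.frame(
    library_strategy = c(rep("WGS", 5), rep("RNA-Seq", 3), rep("WXS", 3),
                         "AMPLICON", "ChIP-Seq", NA))
  tab <- category_counts(joined, "library_strategy", top_n = 3)
  expect_equal(attr(tab, "corpus_total"), 14)
  expect_equal(tab$category[1], "WGS")
  # tie between RNA-Seq and WXS broken lexically
  expect_equal(tab$category[2:3], c("RNA-Seq", "WXS"))
  expect_equal(tab$category[4], "other")
  expect_equal(sum(tab$count), 14)
  expect_true("(missing)" %in%
                category_counts(joined, "library_strategy")$category)
  expect_error(category_counts(joined, "nope"), "unknown field")

  single <- category_counts(data.frame(x = rep("A", 7)), "x")
  expect_equal(single$percent, 100)
})

test_that("category percents sum to 100 within rounding slack", {
  set.seed(73)
  for (rep in 1:5) {
    k <- sample(3:12, 1)
    joined <- data.frame(x = sample(LETTERS[1:k], 500, replace = TRUE))
    tab <- category_counts(joined, "x", top_n = 20)
    expect_lt(abs(sum(tab$percent) - 100), 0.1 * nrow(tab))
  }
})

test_that("log10 histograms bin half-open with exact edge handling", {
  h <- histogram_table(c(1, 10, 100, 1000), scale = "log10",
                       bins = c(0, 1, 2, 3, 4))
  expect_equal(h$count, c(1, 1, 1, 1))
  expect_equal(h$bin_lo, c(1, 10, 100, 1000))
  # single value, one linear bin
  h1 <- histogram_table(5, scale = "linear", bins = 1)
  expect_equal(h1$count, 1)
  expect_true(h1$bin_lo <= 5 && 5 <= h1$bin_hi)
  expect_error(histogram_table(numeric()), "no finite values")
})

test_that("histogram counts plus exclusions account for every value", {
  set.seed(79)
  vals <- c(10^runif(300, 0, 5), -1, 0, NA, Inf)
  h <- histogram_table(vals, scale = "log10", bins = 12)
  ex <- attr(h, "excluded")
  expect_equal(sum(h$count) + ex$non_finite + ex$non_positive, length(vals))
  expect_equal(ex$non_positive, 2)
  expect_equal(ex$non_finite, 2)
})

test_that("log-uniform draws spread evenly over log bins", {
  set.seed(83)
  vals <- 10^runif(1000, 6, 10)
  h <- histogram_table(vals, scale = "log10", bins = c(6, 7, 8, 9, 10))
  # each bin expects 250; 3 sigma of Binomial(1000, 1/4)
  expect_true(all(abs(h$count - 250) < 3 * sqrt(1000 * 0.25 * 0.75)))
})

test_that("faceted histograms partition the total counts", {
  set.seed(89)
  vals <- runif(200, 0, 10)
  fac <- sample(c("GENOMIC", "TRANSCRIPTOMIC"), 200, replace = TRUE)
  h <- histogram_table(vals, bins = 5, facet = fac)
  expect_equal(sum(h$count), 200)
  plain <- histogram_table(vals, bins = 5)
  agg <- tapply(h$count, paste(h$bin_lo), sum)
  expect_equal(as.numeric(agg[as.character(plain$bin_lo)]), plain$count)
})

test_that("threshold fractions use strict comparison", {
  tf <- threshold_fraction(c(0.5, 2.0, 0.0), 1)
  expect_equal(tf$count, 2)
  expect_equal(tf$percent, 66.7)
  expect_equal(threshold_fraction(c(1, 2, 3), 1)$count, 0)  # 1 not < 1
  expect_equal(threshold_fraction(c(1, 2, 3), 1)$percent, 0)
  expect_error(threshold_fraction(numeric(), 1), "no values")
})

test_that("moments use the arithmetic mean and lower median", {
  expect_equal(distribution_moments(c(1, 2, 3)),
               list(mean = 2, median = 2))
  expect_equal(distribution_moments(c(1, 1e9)),
               list(mean = 5.000000005e8, median = 1))
  set.seed(97)
  vals <- rnorm(1e4)
  m <- distribution_moments(vals)
  expect_equal(m$mean, sum(vals) / length(vals))
  expect_equal(m$median, sort(vals)[5000])  # lower of the middle pair
  expect_error(distribution_moments(numeric()), "no values")
})

test_that("quarterly box tables group, sort and summarize by quarter", {
  joined <- data.frame(date = c("2010-01-15", "2010-02-20"),
                       throughput = c(5, 7))
  qb <- quarterly_boxplots(joined, "throughput")
  expect_equal(qb$quarter, "2010-Q1")
  expect_equal(qb$n, 2)
  expect_equal(qb$median, 5)  # lower median
  expect_equal(qb$mean, 6)

  spanning <- data.frame(date = c("2010-11-01", "2011-02-01", "2010-12-31"),
                         v = c(1, 2, 3))
  qb2 <- quarterly_boxplots(spanning, "v")
  expect_equal(qb2$quarter, c("2010-Q4", "2011-Q1"))
  expect_equal(qb2$n, c(2, 1))

  # undated rows excluded and counted; all-undated errors
  withna <- data.frame(date = c("2010-01-01", NA), v = c(1, 2))
  qb3 <- quarterly_boxplots(withna, "v")
  expect_equal(attr(qb3, "excluded"), 1)
  expect_error(quarterly_boxplots(data.frame(date = NA, v = 1), "v"),
               "parseable date")
})

test_that("quartile ordering holds on random quarterly tables", {
  set.seed(101)
  joined <- data.frame(
    date = as.character(as.Date("2012-01-01") +
                          sample.int(720, 300, replace = TRUE)),
    v = rlnorm(300, 8, 2))
  qb <- quarterly_boxplots(joined, "v")
  expect_true(all(diff(match(qb$quarter, sort(qb$quarter))) > 0))
  expect_true(all(qb$q1 <= qb$median & qb$median <= qb$q3))
  expect_true(all(qb$min <= qb$q1 & qb$q3 <= qb$max))
  expect_equal(sum(qb$n), 300)
})

test_that("summaries are pure: identical inputs give identical outputs", {
  corp <- generate_corpus(n_experiments = 200, seed = 7)
  a <- category_counts(corp$joined, "library_strategy")
  b <- category_counts(corp$joined, "library_strategy")
  expect_identical(a, b)
  expect_identical(quarterly_boxplots(corp$joined, "throughput"),
                   quarterly_boxplots(corp$joined, "throughput"))
})
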