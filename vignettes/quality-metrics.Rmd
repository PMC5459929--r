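---
title: "Run quality metrics and repository-scale QC summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run quality metrics and repository-scale QC summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readqc)
```

## What the package computes

Public sequencing archives index submissions by submitter-written metadata,
which supports categorical search but not filtering by data quality. The
remedy is to compute a small set of comparable quality values for every
archived run and attach them to the searchable metadata. `readqc`
implements that pipeline end to end at the level of a single machine: per-run
statistics from FASTQ, run-to-experiment aggregation, a metadata join, and
corpus-level summaries.

The per-run record carries eight run-level values, all derived from four
standard QC report sections:

| value | aggregation over runs | source statistic |
|---|---|---|
| total number of reads | added | basic statistics |
| total bases | added | basic statistics |
| mean / median read length | averaged | length distribution |
| %GC | averaged | basic statistics |
| total duplicate percentage | averaged | duplicate sequences |
| mean / median base call accuracy | averaged | per-position quality |
| N content | averaged | per-position N content |

"Base call accuracy" is a Phred score throughout: `Q = -10 log10(p_error)`,
so a median accuracy of 35 means a median per-base error rate of about
3 in 10,000. It is not a percentage.

## Statistical conventions

All order statistics use one pair of rules, stated once and used everywhere
so that every independent oracle in the test suite is unambiguous:

* **percentiles** use the lower nearest rank: the p-quantile of n values is
  the `ceiling(p * n)`-th smallest;
* **medians** of an even-sized sample take the lower of the two middle
  values.

Printed percentages round **half away from zero** to one decimal. This is
the convention under which published archive-scale shares (36.4%, 18.5%,
20.9%, 46.3%, 94.2%) reproduce exactly from their integer counts; base R's
banker's rounding does not have this property.

`pct_gc` counts G+C over called bases only: N and other IUPAC ambiguity
letters are excluded from numerator and denominator, so GC and AT percent
always sum to 100. Reference QC tools are not explicit on this point; the
called-bases denominator was chosen because it keeps the statistic a
property of successful base calls, independent of the N rate.

## Per-position quality and the run-level accuracy

For each position i, statistics are taken over all reads of length at least
i: mean, lower-nearest-rank median and quartiles of the Phred score. The
run-level `mean_accuracy` is the **unweighted** arithmetic mean of the
per-position means, and `median_accuracy` the lower median of the
per-position medians. The unweighted choice follows from what a flat QC
report exposes — per-position rows, not raw calls — so it is the only rule
that can also be applied consistently when re-parsing an existing report.
A read-coverage-weighted mean (equivalently, the mean over all base calls)
is available via `weighted = TRUE` but is not the default; on runs with
uniform read length the two coincide.

Native computation keeps exact per-position rows. Position binning (rows
like `10-14`) exists only when parsing an external report, where a binned
row is treated as a single entry at its midpoint position; binning is a
display compaction, lossy and version-dependent, and is not reproduced.

## Duplication estimation

Each read is keyed on its sequence, truncated to its first 50 bases when
longer than 75, matching the behaviour of the v0.11 lineage of the
reference QC tool, so long-read chemistry does not defeat exact matching.

Exact mode tallies every distinct key: `dup% = 100 (T - U) / T`.

Capped mode bounds memory: only the first `track_limit` (default 100,000)
distinct keys are tracked, though tracked keys keep counting afterwards.
Let `L` be the number of reads observed when the tracker filled. A key with
final count `c` had probability

$$p(c) = 1 - \prod_{i=0}^{L-1} \frac{T - c - i}{T - i}
       = 1 - \binom{T-c}{L} \Big/ \binom{T}{L}$$

of being seen among the first `L` reads, so each tracked key is up-weighted
by `1/p(c)` (computed stably through `lgamma`, clamped to `(0, 1]`),
giving corrected totals `U* = Σ 1/p(c)`, `T* = Σ c/p(c)` and
`dup% = 100 (1 - U*/T*)`. When the tracker never fills, `p(c) = 1` exactly
and the two modes agree to the bit. The capped estimate depends on read
order by construction (the tracker admits the first keys it meets); every
other metric is order-invariant, and the test suite asserts both facts.

## Aggregation rules

Paired-end mates (`_1`/`_2` files) are measured independently and merged:
read and base totals are summed, every scalar metric averaged. The
length-distribution counts of the mates are summed (this preserves the
invariant that counts sum to `total_reads`), and the per-position tables
are averaged position-wise over the mates covering each position.

Runs aggregate to experiments the same way: totals added, all other metrics
the unweighted mean over runs (`weighted = TRUE` offers a read-weighted
variant). Unweighted is the deliberate default: the experiment record is
meant to answer "what does a typical run of this experiment look like",
not to re-derive corpus-wide per-base averages. `throughput` is defined as
the experiment's summed base total; experiments mixing paired and single
runs need no special rule because each run record is already merged.

## Metadata join

Experiment metadata (library strategy, library source, platform,
instrument model, BioSample link, date) is parsed from SRA experiment XML;
organism metadata (taxonomy id, scientific name) from BioSample XML. Both
parsers match on local element names, so namespace prefixes and element
order never matter. The same columns are accepted as a flat TSV.

The join is a left join on `experiment_id`, then `biosample_id`: quality
records are never dropped or duplicated, unmatched records keep `NA`
categories, and match counts are attached as an attribute. Submitter
metadata is propagated as-is — known to contain errors, but curation is out
of scope.

Two configuration points are data rather than code:

* the **platform-to-manufacturer mapping** (`default_manufacturer_map()`),
  because the archive schema names platforms (`ILLUMINA`, `LS454`, ...)
  while summaries facet by manufacturer, and no authoritative mapping is
  published;
* the **date field** used for time series. Archives carry several dates
  (run, publication, submission) and which one a given summary should bin
  by is a user decision; `quarterly_boxplots()` takes the date column as an
  argument instead of hard-coding one.

## Corpus summaries

`category_counts()` emits a top-N table with descending counts (ties broken
lexically), `NA` grouped as `"(missing)"`, and always an explicit `"other"`
remainder row — dropping the remainder silently would make the percent
column unverifiable. `histogram_table()` bins half-open `[lo, hi)` on a
linear or log10 scale (top bin closed so the maximum survives), counts
excluded non-finite/non-positive values, and optionally facets by a
category. `quarterly_boxplots()` reports the raw five-number summary plus
mean and n per quarter; whisker truncation is a rendering concern and is
deliberately not applied. All summaries are pure functions of the joined
table.

## The synthetic generator

`synthetic_spec()`/`generate_fastq()` emulate the aspects of archived runs
the metrics respond to: read count, a fixed or categorical length model,
per-base GC probability (G/C and A/T equiprobable within their classes),
an independent per-base N rate, a linearly declining Gaussian quality model
`Q_i ~ round(clamp(Normal(mean - slope*(i-1), sd), lo, hi))`, and a
template-pool duplication model (`n_templates` templates emitted
`copies_per_template` times, shuffled). Defaults (1000 reads of length 100,
GC 0.5, quality mean 38 with slope 0.1 and sd 2 clamped to [2, 40])
describe a clean modern short-read run.

Ground truth is **tallied from the emitted reads**, not taken from the
generating probabilities, so deterministic metrics are asserted with exact
equality and only the generator-vs-parameter comparisons carry binomial
tolerances. The generator is deterministic under a fixed seed and restores
the caller's RNG state.

What it does not emulate: platform-specific error profiles, quality-length
correlations, adapter or contamination content, or realistic genome-derived
sequence composition. Passing tests therefore demonstrate the correctness
of the computations, not the behaviour of the metrics on any particular
instrument's artefacts.

`generate_corpus()` generates experiment-level records directly (log-normal
throughput around per-quarter locations, uniform GC/accuracy/duplication in
archive-typical ranges, exponential N content) together with the exact
count tables, moments and quarterly means the summaries must reproduce.

## Numerical and interface choices

* Quality encoding detection: any character below ASCII 59 forces
  Phred+33; otherwise any above 74 indicates Phred+64; fully ambiguous
  files default to Phred+33, the only encoding in use since 2011. The
  generator emits offset 33 only; `reencode_fastq()` produces offset-64
  inputs for detection tests.
* Only the strict 4-line FASTQ dialect is accepted (the form produced by
  `fastq-dump --split-3`); wrapped FASTQ is rejected with a located error
  rather than guessed at. Gzip is detected from magic bytes, not the file
  extension.
* Length-distribution entries may be bins (`"10-14"`), contributing their
  midpoint; overlapping bins are an error.
* The RDF vocabulary is provisional by design: subjects are minted under a
  configurable base URI and every predicate name can be overridden through
  `rdf_mapping()`, because no authoritative public term set is assumed.
  One subject per record, one `xsd:double` triple per metric, plus type
  and identifier triples.

## Problem sizes and limitations

The test suite works at deliberately small scale — randomized files of
tens to hundreds of reads for oracle equivalence (100 files), 10^4 reads
for parameter recovery, 10^3-read pools for duplication, corpora of 10^3
experiments for summary recovery — chosen so the whole suite re-runs in
well under a minute while still leaving the binomial tolerances tight.
Corpus-wide archive statistics (mean/median throughput and accuracy over
the full million-experiment snapshot) require the snapshot itself and are
intentionally outside the package's claims.

Known limitations: the capped duplication correction assumes exchangeable
read order when interpreting `p(c)` (sorted or position-clustered input
biases it, which is inherent to bounded tracking); `parse_fastqc_data()`
recovers binned per-position tables only at bin midpoints; and the
experiment averages are unweighted, so a tiny failed run pulls an
experiment's average as strongly as its main run — use `weighted = TRUE`
when that is not wanted.
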