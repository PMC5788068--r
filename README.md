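# cleanfq

Quality control and preprocessing of single- and paired-end FASTQ data in R:
an integrated "QC → preprocess → QC" workflow with explicit warn/fail
thresholds, deterministic block-parallel execution, and data-type-specific
pipelines for DNA resequencing, digital gene expression (DGE) tags, small
RNA, and metagenomics.

It is written for sequencing-facility and analysis-pipeline users who want a
scriptable, auditable cleaning step: every run records what was removed and
why, statistics of the raw and cleaned data side by side, and a
machine-readable verdict on whether the cleaned data meet quality
expectations.

## What it computes

For every position (cycle) *p* the package accumulates base counts over
{A,C,G,T,N} and a histogram of Phred qualities *q* = −10·log₁₀(e). From
these it reports Q20/Q30 (fraction of bases with *q* ≥ 20 / ≥ 30), GC
content, per-position composition fractions, per-position Q20/Q30, and the
per-position five-number quality summary, using the exact type-1
(inverted-CDF) quantile on the integer histogram. The cleaned data are
judged per position:

* median quality < 25 → **warn**, < 20 → **fail**;
* |A% − T%| or |G% − C%| > 10 percentage points → **warn**, > 20 → **fail**

(strict inequalities; values exactly at a threshold never trigger).

Preprocessing stages, in fixed order: fixed end-trimming → ungapped
mismatch-tolerant 3' adapter localization and cut (default mismatch rate
0.1, min overlap 6, no indels) → module-specific structure handling →
quality end-trimming → a filter battery (batch exclusion, length window,
ambiguous bases, mean quality, low-quality bases) with first-failure reason
attribution, plus optional sequence-identity deduplication. Statistics are
mergeable, so block-parallel runs are byte-identical to serial ones.

## Worked example

```r
library(cleanfq)

# a seeded synthetic paired-end library with known ground truth:
# 10% of pairs carry a planted 3' adapter, 5% are exact duplicates
fx <- generate_fixture(fixture_spec(
  2000, read_len = 90, paired = TRUE,
  adapter = adapter_spec("AGATCGGAAGAGC"),
  adapter_rate = 0.1, dup_rate = 0.05, n_rate = 0.002, seed = 42))
write_fixture(fx, "example_data", "demo")

res <- run_general("example_data/demo_1.fq", "example_data/demo_2.fq",
                   out_dir = "demo_out",
                   adapter = "AGATCGGAAGAGC", qual_trim = 5,
                   filters = filter_spec(dedup = TRUE))
res$verdict
#> <qc_verdict> pass (0 finding(s))
res$raw$n_records; res$clean$n_records
#> [1] 2000
#> [1] 1900
res$clean$filter_tally[res$clean$filter_tally > 0]
#> duplicate
#>       100
```

The 100 planted duplicate pairs are removed and attributed, the planted
adapters are cut at their true offsets (the fixture's `fx$truth` table
records them), and conservation holds: 2000 raw records = 1900 clean + 100
tallied. `demo_out/` now holds the cleaned pair of FASTQ files, a
`summary.json` (raw vs clean counts, Q20/Q30/GC, filter tally, verdict), a
run manifest, and per-mate TSV tables, e.g.:

```r
s <- summarize_stats(res$clean)
sprintf("Q20 %.4f  Q30 %.4f  GC %.4f",
        s$overall$q20, s$overall$q30, s$overall$gc)
#> [1] "Q20 1.0000  Q30 0.9664  GC 0.4987"
head(s$per_position[[1]][, c("position", "depth", "median", "q1", "q3")], 3)
#>   position depth median q1 q3
#> 1        1  1900     35 33 37
#> 2        2  1900     35 33 37
#> 3        3  1900     35 33 37
```

The same run from a shell (exit code 0 = pass/warn, 3 = QC failure):

```sh
Rscript inst/cli/cleanfq general -1 demo_1.fq -2 demo_2.fq -o demo_out \
    --adapter AGATCGGAAGAGC --qual-trim 5 --dedup
```

Module-specific pipelines: `run_dge()` extracts the 17 bp tag after the
first `CATG` anchor and drops tags containing any `N`; `run_srna()` trims
the 3' adapter, removes poly-A contaminants (A fraction ≥ 0.7) and enforces
an 18–30 nt length window; `run_meta()` runs the reduced
trim/length/ambiguity chain. See the methods vignette
(`vignettes/cleanfq-methods.Rmd`) for the models, defaults and design
decisions.

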