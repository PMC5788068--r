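---
title: "Quality control and preprocessing of sequencing reads with cleanfq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control and preprocessing of sequencing reads with cleanfq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleanfq)
```

## The problem

Raw output from high-throughput sequencers is contaminated in predictable
ways: 3' ends read through the insert into the sequencing adapter, terminal
cycles degrade in quality, optical or amplification artifacts produce exact
duplicate reads, whole sequencing batches (Illumina flowcell tiles, BGI
fields of view) can fail collectively, and library-specific structures (tag
anchors in digital gene expression libraries, poly-A carry-over in small-RNA
libraries) need dedicated handling. Every downstream analysis -- alignment,
variant calling, expression counting -- benefits from removing these
artifacts first, and from a quantitative before/after record proving that
the cleaning did what it claims.

`cleanfq` implements this as a single two-pass workflow: per-position and
whole-dataset statistics are computed on the raw input, reads are trimmed,
filtered and transformed in a fixed stage order, the same statistics are
recomputed on the clean output, and the clean statistics are judged against
explicit warn/fail thresholds. All statistics are *mergeable*, so the input
can be processed in fixed-size blocks -- serially or on several worker
processes -- with byte-identical results.

## Statistics and the QC verdict

For each position (cycle) $p$ and each mate, the package accumulates the
count of each base $\{A, C, G, T, N\}$ and a histogram of the integer Phred
quality values $q = -10\log_{10}(e)$, where $e$ is the base-call error
probability. From these it derives:

* whole-dataset Q20 and Q30, the fraction of bases with $q \ge 20$
  ($e \le 1\%$) and $q \ge 30$ ($e \le 0.1\%$), and GC content;
* per-position Q20/Q30 and base-composition fractions (denominator = full
  position depth including `N`, so the five fractions sum to 1);
* the per-position five-number quality summary (min, quartiles, max).

**Quantile rule.** Quantiles are computed from the integer histogram with
the inverted-CDF (type-1) rule: the $q$-quantile is the smallest value whose
cumulative count reaches $\lceil q \cdot \mathrm{depth} \rceil$. On
integer-valued Phred data this is exact, has no interpolation ambiguity, and
is cheap to cross-check against a sort-based oracle (the test suite does so
on every position of randomized fixtures).

**Verdict thresholds.** The clean data (only) is judged per position:

| check | warn | fail |
|---|---|---|
| median quality | $< 25$ | $< 20$ |
| A-vs-T or G-vs-C difference | $> 10$ pp | $> 20$ pp |

All comparisons are strict: a position whose median is exactly 20 or whose
imbalance is exactly 10 percentage points does not trigger. Composition
differences are computed from the integer counts with a single division
(`|A - T| * 100 / depth`) rather than from pre-rounded fractions, so
exact-threshold values are exactly representable -- a subtraction of two
rounded fractions can sit one ulp above the threshold and fire spuriously.
The verdict is `fail` if any fail-level finding exists, `warn` if only
warn-level findings exist, `pass` otherwise. Raw statistics are reported but
never judged; warnings do not change the exit status of the command-line
tool, failures set it to 3.

The check is applied at every nonzero-depth position, including low-depth
trailing cycles; the findings table carries the depth so users can discount
sparse positions themselves. On small datasets the composition check is
sensitive to sampling noise (at depth 60 the A-vs-T difference has a
standard deviation of about 9 pp under a uniform base model), which is the
statistically honest behavior: the check asks whether the *observed* data
are skewed, and tiny datasets genuinely are.

## Adapter localization

The 3' adapter is located by ungapped, mismatch-tolerant alignment. Every
0-based start offset $o$ from 0 to $\mathrm{len} - \mathrm{min\_overlap}$ is
scanned; at each offset the adapter prefix is compared column by column, and
the alignment may overhang the 3' end (aligned length
$= \min(m, \mathrm{len} - o)$ for an adapter of length $m$). A candidate is
valid when its mismatch count is at most
$\lfloor \mathrm{rate} \times \mathrm{aligned\_len} \rfloor$ with defaults
rate $= 0.1$ and min_overlap $= 6$, conventional for 3' adapter trimmers.
`N` on either side is a mismatch. Among valid candidates the smallest
mismatch *rate* wins, ties broken toward the smallest offset (an exact short
overhang match never beats an exact full-length match earlier in the read;
among equally good candidates the cut is made as 5' as possible, the
conservative choice). Rates are compared by integer cross-multiplication so
no floating-point tie ambiguity exists. Insertions and deletions are never
considered; the suite verifies that inserting a single base into a planted
adapter destroys the hit at zero mismatch budget.

Everything from the hit offset to the 3' end is cut. The scan is implemented
in C++ (the only hot loop in the package); an independent, naive R scorer in
the test suite replays 1000 randomized planted/absent/mutated cases against
it.

## Stage order, filters, and attribution

Per read (or pair), stages run in a fixed order: fixed-end trim, adapter
alignment and cut, module-specific structure handling, quality end-trim,
then the filter battery. Adapter detection runs *before* quality trimming so
that it sees the unmutilated 3' sequence. The battery order is: excluded
batch, adapter (only when dropping rather than trimming is requested),
length window, ambiguous-base fraction, mean quality, low-quality-base
fraction. The *first* failing check attributes the drop reason, so the
per-reason tally is deterministic and sums exactly to the number of dropped
records: `raw records = clean records + sum(tally)` is asserted after every
run. For pairs, a check fails when either mate fails it and one verdict
covers the pair, keeping the two output files synchronized (no orphan
reads). Filter thresholds are strict, matching the QC thresholds'
convention. Zero-length reads are legal intermediates (e.g. an adapter hit
at offset 0) and are removed by the length filter; their mean quality is
defined as $+\infty$ and their composition fractions as 0 so that no other
check claims them first.

Basic statistics (reads, bases, Q20/Q30) count individual reads; the filter
tally and the conservation identity count *records* (one pair = one record),
since a pair is dropped as a unit.

## Deduplication

Reads (or pairs) with identical nucleotide sequence -- case-folded, with
qualities ignored and mate order respected -- are reduced to their first
occurrence in stream order. Deduplication is inherently global and
order-dependent, so it runs as a streaming pre-pass with a single shared key
set *before* the input is blocked; per-block stages then stay pure and the
serial/parallel equivalence below holds exactly. A consequence of this
placement is that duplicate identity is defined on the raw (pre-trim)
sequence and the `duplicate` reason takes precedence over the other filter
reasons. Keys are the exact normalized sequence strings held in a hash set:
at the intended (single-machine) scale this is collision-free and the memory
cost is bounded by the unique-sequence count; a hashed digest would save
memory on very large libraries at the cost of an astronomically small
false-duplicate probability.

## Block-parallel execution

Input is streamed in fixed-size blocks (default 100000 records; pairs are
never split across blocks). Each block is processed independently --
optionally on forked worker processes -- and yields kept reads plus raw and
clean statistics deltas. Statistics form a commutative monoid under
`merge_stats()` (elementwise sums with the empty accumulator as identity),
so merged statistics are independent of the blocking; kept reads are written
in ascending block index through one open output connection, which makes
even gzip-compressed output byte-identical between a serial run and any
(workers, block size) combination -- concatenating per-block gzip members
would not be. The suite asserts byte-identical clean FASTQ and reports
across a grid of worker counts and block sizes on a 100000-read fixture.
Output order always equals input order. With merging disabled, per-block
files with zero-padded index suffixes are kept; their concatenation equals
the merged file.

A failure in any block aborts the run naming the block index; all outputs
are staged in a temporary directory and moved into the output directory only
on success, so no partial results are left behind.

## The four modules

* **general** -- the full battery at its documented defaults (min length 18,
  max N fraction 0.05, low-quality base = Phred $< 5$, max low-quality
  fraction 0.5; mean-quality filter and deduplication off).
* **dge** -- digital gene expression tags: single-end reads carry a `CATG`
  anchor (the NlaIII restriction site) followed by a 17 bp target. The
  leftmost anchor occurrence is located and the 17 bases after it are kept
  (anchor excluded by default; `keep_anchor` prepends it for CATG+17
  conventions). Reads without the anchor, or with fewer than 17 bases after
  it, are dropped under a dedicated `dge_tag_missing` reason. Ambiguity
  tolerance is zero (`max_n_fraction = 0`): a single `N` in the tag drops
  the read. The length filter is off because every surviving tag has the
  same length.
* **srna** -- small RNA: inserts (mature miRNAs etc., roughly 18-30 nt) are
  shorter than the read, so the 3' adapter is expected in most reads and is
  trimmed first; reads whose A fraction is at least `polya_fraction`
  (default 0.7, the `>=` side of the threshold) are dropped as poly-A
  (mRNA) contamination under the `polya` reason; then a length window of
  18-30 nt is enforced.
* **meta** -- metagenomics: adapter and quality end-trimming plus the length
  and ambiguous-base filters only; mean-quality and low-quality-base
  filters, deduplication and batch exclusion default to off (explicit
  configuration re-enables any of them).

Module choice alters only stage composition and defaults -- never the I/O
layer or the statistics engine.

## Quality encodings

Quality strings are stored internally in canonical Phred+33 serialization;
the source encoding is provenance only. Auto-detection uses the
disjointness of the two encodings: any character below ASCII 59 proves
Phred+33 (it would decode negative under +64); all characters at or above
64 with at least one above 74 (a Phred+33 score above 41, unseen in real
data) proves Phred+64; anything else falls back to Phred+33 with an
explicit ambiguity warning. Conversion never changes numeric values and is
involutive. Phred+64 output refuses values above 62 (unrepresentable in
printable ASCII), naming the offending read.

## The synthetic-fixture generator

`fixture_spec()`/`generate_fixture()` produce seeded FASTQ with a sidecar
ground-truth table (planted adapter offsets, duplicate source ordinals, DGE
tags, sRNA insert lengths and contaminant flags), keeping the FASTQ itself
free of annotations. Controlled quantities are exact by construction rather
than in expectation:

* Per-position qualities are drawn as symmetric $\pm$ integer offsets
  around the target median (each sampled magnitude planted once with each
  sign, one zero pair pinned), so the type-1 median equals the target at
  any depth $\ge 2$, and clipping to $[0, 41]$ cannot move values across
  the median. This keeps warn/fail boundary scans sharp at a modest
  1000 reads.
* When a composition imbalance of $d$ percentage points is requested, base
  columns are exact shuffled counts: the designated position gets
  $50 + d/2$ percent `A` and $50 - d/2$ percent `T`, all other positions
  exact quarters of `A/C/G/T`. Without the request, bases are uniform
  i.i.d. draws.

The generator emulates the structural features the workflow acts on; it
does **not** emulate platform error profiles (indels, homopolymer errors,
quality-sequence correlation, position-dependent error spectra) or
genome-derived sequence composition. Passing tests therefore demonstrate
the correctness of the bookkeeping, thresholds, alignment and equivalence
contracts -- not performance claims on any particular instrument's data.

## Problem sizes and runtime choices

The test suite works at desk scale, chosen so the full suite completes in
about a minute: boundary scans use 1000 reads per scan point (the exactness
constructions above make larger scans unnecessary), the monoid property is
checked over 200 random three-way splits of a 2000-read set, the
serial/parallel grid runs a 100000-read fixture, oracle comparisons replay
1000 randomized adapter cases, and ground-truth recovery uses up to 10000
reads (where a requested composition bias is required to be recovered
within 1.5 percentage points, the multinomial sampling tolerance at that
depth). The committed worked-example corpora are 60-80 reads each, with
frozen clean output as regression goldens.

## Known limitations

* No gapped or scored (Smith-Waterman) adapter alignment, adapter
  discovery, or 5' adapter handling; no UMI support.
* Orphan rescue is deliberately absent: a pair is dropped as a unit.
* Desynchronized paired files are an error at the first offending record,
  not re-paired.
* Only 4-line FASTQ with Phred+33/+64 encodings is supported (no multi-line
  records, SAM/BAM, or FASTA input).
* Deduplication considers reads in the orientation given; reverse-complement
  duplicates are distinct.
* The per-read quality and length distributions, DGE singleton filtering
  and sRNA ncRNA-database screening are out of scope.
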