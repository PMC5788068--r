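Package: cleanfq
Title: Quality Control and Preprocessing of High-Throughput Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated quality-control and preprocessing workflow for
    single- and paired-end FASTQ data: two-pass per-position quality and
    base-composition statistics with explicit warn/fail thresholds,
    mismatch-tolerant ungapped 3' adapter trimming, fixed and quality-based
    end trimming, multi-criterion read filtering with per-reason tallies,
    sequencing-batch (tile/fov) exclusion, sequence-identity deduplication,
    and data-type-specific pipelines for DNA resequencing, digital gene
    expression tags, small RNA, and metagenomics. Statistics accumulators
    are mergeable, so processing in fixed-size blocks (optionally across
    worker processes) is byte-identical to a serial run. A seeded synthetic
    FASTQ generator with recorded ground truth supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    parallel,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
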