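#' Adapter specification
#'
#' Describes the 3' sequencing adapter and the tolerance of the ungapped
#' alignment used to locate it: at most `floor(max_mismatch_rate *
#' aligned_len)` mismatching columns, over at least `min_overlap` aligned
#' columns. Insertions and deletions are never considered.
#'
#' @param sequence adapter bases (string over `ACGT`), or the path of a
#'   single-record FASTA file.
#' @param max_mismatch_rate maximum fraction of mismatching columns
#'   (default 0.1).
#' @param min_overlap minimum aligned columns for a hit (default 6).
#' @return An `adapter_spec` list.
#' @export
adapter_spec <- function(sequence, max_mismatch_rate = 0.1, min_overlap = 6L) {
  sequence <- adapter_sequence(sequence)
  stopifnot(max_mismatch_rate >= 0, max_mismatch_rate < 0.5,
            min_overlap >= 1L, min_overlap <= nchar(sequence))
  structure(list(sequence = sequence,
                 max_mismatch_rate = max_mismatch_rate,
                 min_overlap = as.integer(min_overlap)),
            class = "adapter_spec")
}

#' Locate a 3' adapter in each read by ungapped mismatch-tolerant alignment
#'
#' Every 0-based start offset from 0 to `length - min_overlap` is scanned.
#' At each offset the adapter prefix is compared to the read column by
#' column (the alignment may overhang the 3' end of the read); `N` counts
#' as a mismatch. A candidate is valid when its mismatch count is at most
#' `floor(max_mismatch_rate * aligned_len)`. The valid candidate with the
#' smallest mismatch rate wins; ties are broken by the smallest offset.
#'
#' @param reads an `fq_reads` object.
#' @param spec an [adapter_spec()].
#' @return Data frame with one row per read: `offset` (0-based start of the
#'   adapter in the read, `NA` when no hit), `aligned_len`, `mismatches`.
#' @export
align_adapter <- function(reads, spec) {
  stopifnot(inherits(spec, "adapter_spec"))
  hits <- cpp_align_adapter(reads$seq, spec$sequence,
                            spec$max_mismatch_rate, spec$min_overlap)
  as.data.frame(hits)
}

#' Cut an aligned adapter (and everything 3' of it) off each read
#'
#' @param reads an `fq_reads` object.
#' @param hits result of [align_adapter()] on the same reads; rows with
#'   `NA` offset leave the read unchanged.
#' @return The trimmed `fq_reads`.
#' @export
trim_adapter <- function(reads, hits) {
  hit <- !is.na(hits$offset)
  if (any(hit)) {
    reads$seq[hit] <- substr(reads$seq[hit], 1L, hits$offset[hit])
    reads$qual[hit] <- substr(reads$qual[hit], 1L, hits$offset[hit])
  }
  reads
}

#' Trim a fixed number of bases from the read ends
#'
#' @param reads an `fq_reads` object.
#' @param head_fixed bases removed from the 5' end.
#' @param tail_fixed bases removed from the 3' end. If the two overlap the
#'   read becomes zero-length (removed downstream by the length filter).
#' @return The trimmed `fq_reads`.
#' @export
trim_fixed_ends <- function(reads, head_fixed = 0L, tail_fixed = 0L) {
  stopifnot(head_fixed >= 0L, tail_fixed >= 0L)
  if (head_fixed == 0L && tail_fixed == 0L) return(reads)
  len <- nchar(reads$seq)
  from <- pmin(head_fixed + 1L, len + 1L)
  to <- len - tail_fixed
  reads$seq <- substr(reads$seq, from, to)
  reads$qual <- substr(reads$qual, from, to)
  reads
}

#' Trim low-quality bases off both read ends
#'
#' Bases with quality strictly below the threshold are removed from the 5'
#' end, then from the 3' end; interior bases are never touched. After
#' trimming, any surviving terminal base has quality at or above the
#' threshold.
#'
#' @param reads an `fq_reads` object.
#' @param qual_threshold Phred threshold; 0 disables trimming.
#' @return The trimmed `fq_reads`.
#' @export
trim_low_quality_ends <- function(reads, qual_threshold = 0L) {
  if (qual_threshold <= 0L || length(reads) == 0L) return(reads)
  b <- cpp_qual_trim_bounds(reads$qual, as.integer(qual_threshold))
  reads$seq <- substr(reads$seq, b[, 1], b[, 2])
  reads$qual <- substr(reads$qual, b[, 1], b[, 2])
  reads
}

#' Per-read quality and composition metrics
#'
#' `mean_quality` is the arithmetic mean Phred score of a read (zero-length
#' reads report `Inf`, so they never fail the mean-quality filter — they are
#' removed by the length filter instead). `ambiguous_fraction` is the
#' fraction of `N` bases; `low_quality_fraction` the fraction of bases with
#' quality strictly below `low_qual_value`. Fractions of zero-length reads
#' are 0.
#'
#' @param reads an `fq_reads` object.
#' @param low_qual_value Phred value below which a base counts as
#'   low-quality.
#' @return Numeric vector, one value per read.
#' @export
mean_quality <- function(reads) {
  vapply(qual_ints(reads), function(q) {
    if (length(q)) mean(q) else Inf
  }, numeric(1))
}

#' @rdname mean_quality
#' @export
ambiguous_fraction <- function(reads) {
  len <- nchar(reads$seq)
  nn <- nchar(reads$seq) - nchar(gsub("[Nn]", "", reads$seq))
  ifelse(len > 0L, nn / len, 0)
}

#' @rdname mean_quality
#' @export
low_quality_fraction <- function(reads, low_qual_value = 5L) {
  vapply(qual_ints(reads), function(q) {
    if (length(q)) mean(q < low_qual_value) else 0
  }, numeric(1))
}

#' Filtering specification
#'
#' Thresholds for the read-filter battery. All comparisons are strict: a
#' read is dropped only when it is strictly beyond a threshold, never when
#' it sits exactly on one.
#'
#' @param min_length minimum surviving length after trimming (default 18).
#' @param max_length maximum length (default `Inf`; the small-RNA pipeline
#'   sets 30).
#' @param max_n_fraction maximum fraction of `N` bases (default 0.05).
#' @param min_mean_quality minimum mean Phred score (default 0 = off).
#' @param low_qual_value Phred value defining a low-quality base
#'   (default 5).
#' @param max_low_qual_fraction maximum fraction of low-quality bases
#'   (default 0.5).
#' @param drop_adapter_reads drop reads in which an adapter was found
#'   instead of trimming them.
#' @param excluded_batches character vector of batch labels (tiles or fovs)
#'   whose reads are discarded.
#' @param batch_kind `"tile"` or `"fov"`.
#' @param dedup drop records whose nucleotide sequence was seen before.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_length = 18L, max_length = Inf,
                        max_n_fraction = 0.05, min_mean_quality = 0,
                        low_qual_value = 5L, max_low_qual_fraction = 0.5,
                        drop_adapter_reads = FALSE,
                        excluded_batches = character(),
                        batch_kind = "tile", dedup = FALSE) {
  stopifnot(min_length >= 0, max_n_fraction >= 0, max_n_fraction <= 1,
            max_low_qual_fraction >= 0, max_low_qual_fraction <= 1,
            min_mean_quality >= 0, low_qual_value >= 0)
  structure(list(min_length = min_length, max_length = max_length,
                 max_n_fraction = max_n_fraction,
                 min_mean_quality = min_mean_quality,
                 low_qual_value = low_qual_value,
                 max_low_qual_fraction = max_low_qual_fraction,
                 drop_adapter_reads = isTRUE(drop_adapter_reads),
                 excluded_batches = as.character(excluded_batches),
                 batch_kind = batch_kind, dedup = isTRUE(dedup)),
            class = "filter_spec")
}

#' Apply the filter battery to trimmed reads or pairs
#'
#' Checks run in a fixed order — excluded batch, adapter (only when
#' `drop_adapter_reads` is set), length window, ambiguous bases, mean
#' quality, low-quality bases — and the first failing check attributes the
#' drop reason, so per-reason tallies are deterministic and sum exactly to
#' the number of dropped records. For pairs, a check fails when either mate
#' fails it, and one verdict covers the pair.
#'
#' @param r1 an `fq_reads` object (mate 1, or single-end reads).
#' @param r2 optional `fq_reads` for mate 2, parallel to `r1`.
#' @param spec a [filter_spec()].
#' @param adapter_found logical per record: adapter located in either mate.
#' @param batch character per record: batch label, `NA` when absent.
#' @return Data frame with logical `keep` and character `reason` (`NA` for
#'   kept records).
#' @export
apply_filters <- function(r1, r2 = NULL, spec = filter_spec(),
                          adapter_found = NULL, batch = NULL) {
  n <- length(r1)
  reason <- rep(NA_character_, n)
  claim <- function(mask, why) {
    sel <- mask & is.na(reason)
    reason[sel] <<- why
  }
  either <- function(f, ...) {
    # a check fails when EITHER mate fails it
    v <- f(r1, ...)
    if (!is.null(r2)) v <- v | f(r2, ...)
    v
  }
  worst_high <- function(f, ...) {
    v <- f(r1, ...)
    if (!is.null(r2)) v <- pmax(v, f(r2, ...))
    v
  }
  worst_low <- function(f, ...) {
    v <- f(r1, ...)
    if (!is.null(r2)) v <- pmin(v, f(r2, ...))
    v
  }
  if (length(spec$excluded_batches) && !is.null(batch)) {
    claim(!is.na(batch) & batch %in% spec$excluded_batches, "excluded_batch")
  }
  if (spec$drop_adapter_reads && !is.null(adapter_found)) {
    claim(adapter_found, "adapter")
  }
  bad_len <- function(r) {
    len <- nchar(r$seq)
    len < spec$min_length | len > spec$max_length
  }
  claim(either(bad_len), "short_length")
  if (spec$max_n_fraction < 1) {
    claim(worst_high(ambiguous_fraction) > spec$max_n_fraction,
          "ambiguous_bases")
  }
  if (spec$min_mean_quality > 0) {
    claim(worst_low(mean_quality) < spec$min_mean_quality, "low_mean_quality")
  }
  if (spec$max_low_qual_fraction < 1) {
    claim(worst_high(low_quality_fraction, spec$low_qual_value) >
            spec$max_low_qual_fraction, "low_quality_bases")
  }
  data.frame(keep = is.na(reason), reason = reason)
}

#' Sequence-identity key of a read or pair
#'
#' Deduplication considers nucleotide content only: identical bases (case
#' folded, qualities ignored) give identical keys. For pairs the key joins
#' the two mates with a separator, so mate order matters.
#'
#' @param r1 an `fq_reads` object.
#' @param r2 optional mate-2 `fq_reads`.
#' @return Character vector of keys.
#' @export
dedup_key <- function(r1, r2 = NULL) {
  k <- toupper(r1$seq)
  if (!is.null(r2)) k <- paste(k, toupper(r2$seq), sep = "|")
  k
}

#' Create a deduplication state
#'
#' The state is a hash set of sequence keys shared across all blocks of a
#' run, so first-occurrence semantics are global and independent of the
#' block size.
#'
#' @return An environment used by [mark_duplicates()].
#' @export
dedup_state <- function() new.env(parent = emptyenv(), hash = TRUE)

#' Mark records whose sequence key was already seen
#'
#' First occurrences (in stream order) are recorded in the state and
#' reported as non-duplicates; later occurrences are flagged. Also resolves
#' duplicates within the supplied batch.
#'
#' @param keys character vector from [dedup_key()].
#' @param state a [dedup_state()].
#' @return Logical vector: `TRUE` where the record is a duplicate.
#' @export
mark_duplicates <- function(keys, state) {
  seen_before <- vapply(keys, exists, logical(1),
                        envir = state, inherits = FALSE, USE.NAMES = FALSE)
  first_here <- !duplicated(keys)
  dup <- seen_before | !first_here
  new_keys <- keys[!seen_before & first_here]
  for (k in new_keys) assign(k, TRUE, envir = state)
  dup
}

#' Interconvert DNA and RNA base alphabets
#'
#' `dna_to_rna` maps `T`/`t` to `U`/`u`; `rna_to_dna` maps back. All other
#' characters and all quality values are unchanged; the two modes are
#' mutually inverse.
#'
#' @param reads an `fq_reads` object.
#' @param mode `"dna_to_rna"` or `"rna_to_dna"`.
#' @return The transformed `fq_reads`.
#' @export
transform_sequence <- function(reads, mode = c("dna_to_rna", "rna_to_dna")) {
  mode <- match.arg(mode)
  reads$seq <- if (mode == "dna_to_rna") {
    chartr("Tt", "Uu", reads$seq)
  } else {
    chartr("Uu", "Tt", reads$seq)
  }
  reads
}
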