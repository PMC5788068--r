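#' Specification of a synthetic FASTQ fixture
#'
#' Describes a seeded synthetic dataset with recorded ground truth: planted
#' 3' adapters at known offsets, exact duplicates of earlier reads, per-base
#' ambiguity, controlled per-position quality medians and base-composition
#' imbalance, and module-specific read structure (anchored DGE tags, short
#' small-RNA inserts with poly-A contaminants).
#'
#' Controlled quantities are exact by construction, not just in expectation:
#'
#' * Quality values at each position are drawn as a symmetric set of
#'   integer offsets around the target median (each sampled magnitude is
#'   planted once with `+` and once with `-` sign, with at least one zero
#'   pair), so the inverted-CDF median of every position equals the target
#'   exactly at any even depth, and clipping to `[0, 41]` cannot shift it.
#' * When a composition imbalance is requested, base counts at every
#'   position are exact counts (shuffled across reads), not multinomial
#'   draws: the designated position holds `50 + d/2` percent `A` and
#'   `50 - d/2` percent `T`, all other positions hold equal quarters of
#'   `A/C/G/T`.
#'
#' @param n_reads number of reads (or pairs).
#' @param read_len read length in bases.
#' @param paired generate paired-end data.
#' @param qual_median target per-position median Phred score; scalar or a
#'   vector of length `read_len`.
#' @param qual_spread standard deviation of the symmetric integer offsets
#'   around the median (Phred units).
#' @param adapter an [adapter_spec()] (or adapter string) planted into a
#'   fraction `adapter_rate` of reads by overwriting the read suffix from a
#'   recorded offset.
#' @param adapter_rate fraction of reads receiving a planted adapter.
#' @param adapter_offset_range inclusive 0-based range the planted adapter
#'   start offset is drawn from.
#' @param dup_rate fraction of reads that are exact sequence copies of an
#'   earlier read (qualities are re-drawn: duplication is defined on
#'   nucleotides only).
#' @param n_rate per-base probability of an `N`.
#' @param composition_bias `NULL`, or `list(position =, delta =, pair =)`
#'   with `delta` the A-vs-T (or G-vs-C) imbalance in percentage points at
#'   the 1-based `position`.
#' @param module_structure `"none"`, `"dge"` (random prefix + anchor +
#'   N-free tag + suffix) or `"srna"` (18-30 nt insert + planted adapter,
#'   plus poly-A contaminants).
#' @param dge_anchor,dge_tag_len DGE structure parameters.
#' @param contaminant_rate fraction of poly-A contaminant reads (`srna`).
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_reads, read_len = 90L, paired = FALSE,
                         qual_median = 35L, qual_spread = 3,
                         adapter = NULL, adapter_rate = 0,
                         adapter_offset_range = NULL,
                         dup_rate = 0, n_rate = 0,
                         composition_bias = NULL,
                         module_structure = c("none", "dge", "srna"),
                         dge_anchor = "CATG", dge_tag_len = 17L,
                         contaminant_rate = 0.1, seed = 1L) {
  module_structure <- match.arg(module_structure)
  if (!is.null(adapter) && !inherits(adapter, "adapter_spec")) {
    adapter <- adapter_spec(adapter)
  }
  stopifnot(n_reads >= 1L, read_len >= 1L,
            adapter_rate >= 0, adapter_rate <= 1,
            dup_rate >= 0, dup_rate <= 1, n_rate >= 0, n_rate <= 1)
  if (is.null(adapter_offset_range)) {
    adapter_offset_range <- c(max(1L, read_len - 40L), read_len - 6L)
  }
  if (!is.null(adapter) && adapter_rate > 0 &&
      adapter_offset_range[1] >= read_len) {
    stop("adapter offset range lies beyond the read length")
  }
  structure(list(n_reads = as.integer(n_reads), read_len = as.integer(read_len),
                 paired = isTRUE(paired), qual_median = qual_median,
                 qual_spread = qual_spread, adapter = adapter,
                 adapter_rate = adapter_rate,
                 adapter_offset_range = as.integer(adapter_offset_range),
                 dup_rate = dup_rate, n_rate = n_rate,
                 composition_bias = composition_bias,
                 module_structure = module_structure,
                 dge_anchor = toupper(dge_anchor),
                 dge_tag_len = as.integer(dge_tag_len),
                 contaminant_rate = contaminant_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Symmetric integer quality sampler with an exact inverted-CDF median:
# magnitudes are planted in +/- pairs (first pair pinned at zero), so at any
# depth >= 2 the cumulative count at the target value passes ceiling(n/2).
sample_sym_quals <- function(n, median_q, spread) {
  half <- n %/% 2L
  mags <- if (half > 0L) abs(round(stats::rnorm(half, 0, spread))) else integer()
  if (half > 0L) mags[1] <- 0L
  offs <- c(mags, -mags)
  if (n %% 2L == 1L) offs <- c(offs, 0L)
  offs <- sample(offs)
  as.integer(pmin(pmax(median_q + offs, 0L), 41L))
}

# Exact-count base column: counts per A/C/G/T/N, shuffled across reads.
exact_base_column <- function(counts) {
  sample(rep(BASE_LEVELS, times = counts))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic FASTQ fixture with ground truth
#'
#' @param spec a [fixture_spec()].
#' @return A list with `r1` (and `r2` when paired) as `fq_reads`, and
#'   `truth`: a data frame with one row per read — `ordinal`,
#'   `adapter_offset` (0-based planted offset or `NA`), `duplicate_of`
#'   (1-based ordinal of the copied read or `NA`), `tag` (planted DGE tag),
#'   `insert_len` (sRNA), and `polya` (contaminant flag).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)
  n <- spec$n_reads
  L <- spec$read_len
  truth <- data.frame(ordinal = seq_len(n),
                      adapter_offset = rep(NA_integer_, n),
                      duplicate_of = rep(NA_integer_, n),
                      tag = rep(NA_character_, n),
                      insert_len = rep(NA_integer_, n),
                      polya = rep(FALSE, n))
  gen_mate <- function(record_truth) {
    # base matrix, one column per position
    cols <- vector("list", L)
    balanced <- !is.null(spec$composition_bias)
    for (p in seq_len(L)) {
      if (balanced) {
        cb <- spec$composition_bias
        if (p == cb$position) {
          pair <- if (is.null(cb$pair)) "AT" else cb$pair
          hi <- round(n * (50 + cb$delta / 2) / 100)
          lo <- n - hi
          counts <- stats::setNames(integer(5), BASE_LEVELS)
          counts[substr(pair, 1, 1)] <- hi
          counts[substr(pair, 2, 2)] <- lo
          cols[[p]] <- exact_base_column(counts)
        } else {
          q <- n %/% 4L
          counts <- c(A = q, C = q, G = q, T = n - 3L * q, N = 0L)
          cols[[p]] <- exact_base_column(counts)
        }
      } else {
        cols[[p]] <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      }
    }
    mat <- do.call(cbind, cols)
    # module structure rewrites whole reads
    if (spec$module_structure == "dge" && record_truth) {
      alen <- nchar(spec$dge_anchor)
      for (i in seq_len(n)) {
        max_pre <- L - alen - spec$dge_tag_len
        pre <- sample.int(max_pre + 1L, 1L) - 1L
        tag <- random_bases(spec$dge_tag_len)
        repeat {
          prefix <- if (pre > 0L) random_bases(pre) else ""
          if (!grepl(spec$dge_anchor, prefix, fixed = TRUE)) break
        }
        suffix_len <- L - pre - alen - spec$dge_tag_len
        suffix <- if (suffix_len > 0L) random_bases(suffix_len) else ""
        row <- strsplit(paste0(prefix, spec$dge_anchor, tag, suffix), "")[[1]]
        mat[i, ] <- row
        truth$tag[i] <<- tag
      }
    }
    if (spec$module_structure == "srna" && record_truth) {
      stopifnot(!is.null(spec$adapter))
      aseq <- strsplit(spec$adapter$sequence, "")[[1]]
      n_cont <- round(spec$contaminant_rate * n)
      cont <- if (n_cont > 0) sample.int(n, n_cont) else integer()
      for (i in seq_len(n)) {
        ins_len <- sample(18:30, 1L)
        ins <- if (i %in% cont) {
          rep("A", ins_len)
        } else {
          strsplit(random_bases(ins_len), "")[[1]]
        }
        fill <- L - ins_len
        tail_part <- c(aseq, strsplit(random_bases(max(fill, 1)), "")[[1]])
        mat[i, ] <- c(ins, tail_part[seq_len(fill)])
        truth$insert_len[i] <<- ins_len
        truth$adapter_offset[i] <<- ins_len
        truth$polya[i] <<- i %in% cont
      }
    }
    # planted adapters (general module structure)
    if (!is.null(spec$adapter) && spec$adapter_rate > 0 &&
        spec$module_structure == "none" && record_truth) {
      n_ad <- round(spec$adapter_rate * n)
      who <- if (n_ad > 0) sort(sample.int(n, n_ad)) else integer()
      rng <- spec$adapter_offset_range
      aseq <- strsplit(spec$adapter$sequence, "")[[1]]
      for (i in who) {
        off <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
        span <- seq.int(off + 1L, min(L, off + length(aseq)))
        mat[i, span] <- aseq[seq_along(span)]
        truth$adapter_offset[i] <<- off
      }
    }
    # ambiguous bases
    if (spec$n_rate > 0) {
      mask <- matrix(stats::runif(n * L) < spec$n_rate, nrow = n)
      mat[mask] <- "N"
    }
    # duplicates: later reads copy the full base string of an earlier read
    if (spec$dup_rate > 0 && record_truth) {
      n_dup <- round(spec$dup_rate * n)
      if (n_dup > 0 && n >= 2L) {
        dups <- sort(sample(2:n, n_dup))
        for (i in dups) {
          src <- sample.int(i - 1L, 1L)
          mat[i, ] <- mat[src, ]
          truth$duplicate_of[i] <<- src
          truth$adapter_offset[i] <<- truth$adapter_offset[src]
          truth$polya[i] <<- truth$polya[src]
        }
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    med <- rep(spec$qual_median, length.out = L)
    qmat <- vapply(seq_len(L),
                   function(p) sample_sym_quals(n, med[p], spec$qual_spread),
                   integer(n))
    if (n == 1L) qmat <- matrix(qmat, nrow = 1L)
    quals <- vapply(seq_len(n),
                    function(i) encode_phred33(qmat[i, ]), character(1))
    fq_reads(sprintf("sim:%06d", seq_len(n)), seqs, quals)
  }
  r1 <- gen_mate(record_truth = TRUE)
  out <- list(r1 = r1, truth = truth)
  if (spec$paired) {
    r2 <- gen_mate(record_truth = FALSE)
    r2$id <- r1$id
    # a duplicate pair must duplicate both mates
    dups <- which(!is.na(truth$duplicate_of))
    for (i in dups) r2$seq[i] <- r2$seq[truth$duplicate_of[i]]
    out$r2 <- r2
  }
  out
}

#' Write a generated fixture to disk
#'
#' Emits the FASTQ file(s) and a sidecar tab-separated ground-truth table
#' (one row per read), keeping the FASTQ itself free of annotations.
#'
#' @param fx result of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param gzip gzip-compress the FASTQ output.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fx, dir, prefix = "fixture", gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fq.gz" else ".fq"
  paths <- character()
  if (!is.null(fx$r2)) {
    p1 <- file.path(dir, paste0(prefix, "_1", ext))
    p2 <- file.path(dir, paste0(prefix, "_2", ext))
    write_fastq(fx$r1, p1)
    write_fastq(fx$r2, p2)
    paths <- c(p1, p2)
  } else {
    p1 <- file.path(dir, paste0(prefix, ext))
    write_fastq(fx$r1, p1)
    paths <- p1
  }
  tp <- file.path(dir, paste0(prefix, ".truth.tsv"))
  utils::write.table(fx$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tp))
}

#' Build a controlled QC scan dataset
#'
#' A dataset purpose-built for threshold scans: every position has an exact
#' median quality and exactly balanced base composition, except one
#' designated position whose median quality or A-vs-T imbalance is set to a
#' controlled value. Used to locate the QC warn/fail cut points empirically.
#'
#' @param n_reads number of reads (even values make medians exact).
#' @param read_len read length.
#' @param position the controlled 1-based position.
#' @param median_at target median quality at the controlled position.
#' @param median_elsewhere median quality everywhere else.
#' @param imbalance A-vs-T imbalance in percentage points at the controlled
#'   position (0 = balanced).
#' @param seed integer seed.
#' @return An `fq_reads` object.
#' @export
qc_scan_reads <- function(n_reads = 1000L, read_len = 36L, position = 10L,
                          median_at = 35L, median_elsewhere = 35L,
                          imbalance = 0, seed = 1L) {
  med <- rep(median_elsewhere, read_len)
  med[position] <- median_at
  spec <- fixture_spec(n_reads, read_len, qual_median = med,
                       qual_spread = 3,
                       composition_bias = list(position = position,
                                               delta = imbalance,
                                               pair = "AT"),
                       seed = seed)
  generate_fixture(spec)$r1
}
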