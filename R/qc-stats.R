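BASE_LEVELS <- c("A", "C", "G", "T", "N")
MAX_PHRED <- 93L

FILTER_REASONS <- c("excluded_batch", "duplicate", "adapter",
                    "dge_tag_missing", "polya", "short_length",
                    "ambiguous_bases", "low_mean_quality",
                    "low_quality_bases")

#' Create an empty dataset statistics accumulator
#'
#' `dataset_stats` is the mergeable unit of all QC in this package: read,
#' base, Q20/Q30 and per-base-composition counters plus, per mate, a
#' position-indexed base-count matrix and quality-value histogram. Two
#' accumulators built from disjoint read sets merge (with [merge_stats()])
#' into exactly the accumulator of the union, which is what makes
#' block-parallel processing equivalent to a serial pass.
#'
#' @param paired `TRUE` for paired-end data (two per-mate accumulators).
#' @return A `dataset_stats` object with all counters zero.
#' @export
new_dataset_stats <- function(paired = FALSE) {
  mate <- function() list(
    base_counts = matrix(0, nrow = 5L, ncol = 0L,
                         dimnames = list(BASE_LEVELS, NULL)),
    qual_hist = matrix(0, nrow = MAX_PHRED + 1L, ncol = 0L,
                       dimnames = list(0:MAX_PHRED, NULL)))
  structure(list(
    paired = paired,
    n_records = 0,
    n_reads = 0,
    n_bases = 0,
    base_totals = stats::setNames(numeric(5), BASE_LEVELS),
    q20_bases = 0,
    q30_bases = 0,
    filter_tally = stats::setNames(numeric(length(FILTER_REASONS)),
                                   FILTER_REASONS),
    pos = if (paired) list(mate(), mate()) else list(mate())
  ), class = "dataset_stats")
}

grow_cols <- function(m, ncol_new) {
  if (ncol(m) >= ncol_new) return(m)
  cbind(m, matrix(0, nrow = nrow(m), ncol = ncol_new - ncol(m)))
}

#' Accumulate a set of reads into a statistics object
#'
#' Updates read/base counts, base-composition totals, Q20/Q30 counters and
#' the per-position base and quality histograms. For paired data call once
#' per mate; the record (pair) counter is incremented on mate 1 only.
#' `U` (after an RNA transform) is tallied as `T`; any other non-ACGT
#' character is tallied as `N`.
#'
#' @param stats a `dataset_stats` object.
#' @param reads an `fq_reads` object.
#' @param mate 1 or 2.
#' @return The updated `dataset_stats`.
#' @export
accumulate_stats <- function(stats, reads, mate = 1L) {
  n <- length(reads)
  if (mate == 1L) stats$n_records <- stats$n_records + n
  if (n == 0L) return(stats)
  lens <- nchar(reads$seq)
  stats$n_reads <- stats$n_reads + n
  stats$n_bases <- stats$n_bases + sum(lens)
  L <- max(lens)
  ps <- stats$pos[[mate]]
  ps$base_counts <- grow_cols(ps$base_counts, L)
  ps$qual_hist <- grow_cols(ps$qual_hist, L)
  seqs <- chartr("acgtnuU", "ACGTNTT", reads$seq)
  base_delta <- matrix(0, nrow = 5L, ncol = L)
  qual_delta <- matrix(0, nrow = MAX_PHRED + 1L, ncol = L)
  for (p in seq_len(L)) {
    bs <- substr(seqs, p, p)
    bs <- bs[nzchar(bs)]
    idx <- match(bs, BASE_LEVELS[1:4])
    idx[is.na(idx)] <- 5L
    base_delta[, p] <- tabulate(idx, 5L)
    qs <- substr(reads$qual, p, p)
    qs <- qs[nzchar(qs)]
    if (length(qs)) {
      codes <- utf8ToInt(paste(qs, collapse = "")) - 33L
      qual_delta[, p] <- tabulate(codes + 1L, MAX_PHRED + 1L)
    }
  }
  ps$base_counts[, seq_len(L)] <- ps$base_counts[, seq_len(L), drop = FALSE] +
    base_delta
  ps$qual_hist[, seq_len(L)] <- ps$qual_hist[, seq_len(L), drop = FALSE] +
    qual_delta
  stats$pos[[mate]] <- ps
  stats$base_totals <- stats$base_totals + rowSums(base_delta)
  stats$q20_bases <- stats$q20_bases + sum(qual_delta[-(1:20), ])
  stats$q30_bases <- stats$q30_bases + sum(qual_delta[-(1:30), ])
  stats
}

#' Record dropped records in the filter tally
#'
#' @param stats a `dataset_stats` object.
#' @param reasons character vector of filter reasons (one per dropped
#'   record), drawn from the package's reason vocabulary.
#' @return The updated `dataset_stats`.
#' @export
tally_filtered <- function(stats, reasons) {
  if (length(reasons) == 0L) return(stats)
  tab <- table(reasons)
  nm <- names(tab)
  unknown <- setdiff(nm, names(stats$filter_tally))
  if (length(unknown)) {
    stats$filter_tally[unknown] <- 0
  }
  stats$filter_tally[nm] <- stats$filter_tally[nm] + as.numeric(tab)
  stats
}

#' Merge two statistics accumulators
#'
#' Elementwise sum of every counter. The operation is associative and
#' commutative with [new_dataset_stats()] as identity, so any blockwise
#' split of the input yields the same merged statistics as one serial pass.
#'
#' @param a,b `dataset_stats` objects built under the same mate structure.
#' @return The merged `dataset_stats`.
#' @export
merge_stats <- function(a, b) {
  if (!identical(a$paired, b$paired)) {
    stop("cannot merge statistics with different mate structures")
  }
  out <- a
  out$n_records <- a$n_records + b$n_records
  out$n_reads <- a$n_reads + b$n_reads
  out$n_bases <- a$n_bases + b$n_bases
  out$base_totals <- a$base_totals + b$base_totals
  out$q20_bases <- a$q20_bases + b$q20_bases
  out$q30_bases <- a$q30_bases + b$q30_bases
  keys <- union(names(a$filter_tally), names(b$filter_tally))
  ft <- stats::setNames(numeric(length(keys)), keys)
  ft[names(a$filter_tally)] <- a$filter_tally
  ft[names(b$filter_tally)] <- ft[names(b$filter_tally)] + b$filter_tally
  out$filter_tally <- ft
  for (m in seq_along(a$pos)) {
    L <- max(ncol(a$pos[[m]]$base_counts), ncol(b$pos[[m]]$base_counts))
    out$pos[[m]]$base_counts <- grow_cols(a$pos[[m]]$base_counts, L) +
      grow_cols(b$pos[[m]]$base_counts, L)
    out$pos[[m]]$qual_hist <- grow_cols(a$pos[[m]]$qual_hist, L) +
      grow_cols(b$pos[[m]]$qual_hist, L)
  }
  out
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf(
    "<dataset_stats> %s: %d record(s), %d read(s), %d base(s)\n",
    if (x$paired) "paired-end" else "single-end",
    x$n_records, x$n_reads, x$n_bases))
  invisible(x)
}

# Inverted-CDF (type-1) quantile of an integer histogram: the smallest value
# whose cumulative count reaches ceiling(p * depth). Exact on Phred integers.
hist_quantile <- function(counts, p) {
  depth <- sum(counts)
  if (depth == 0) return(NA_real_)
  target <- ceiling(p * depth)
  if (target < 1) target <- 1
  vals <- as.integer(rownames(counts) %||% seq_along(counts) - 1L)
  vals[which(cumsum(counts) >= target)[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a statistics accumulator
#'
#' Computes whole-dataset ratios (Q20, Q30, GC) and, per mate, a
#' position-indexed table of depth, base composition fractions, per-position
#' Q20/Q30 and the five-number quality summary (min, lower quartile, median,
#' upper quartile, max). Quantiles use the inverted-CDF (type-1) rule on the
#' integer quality histogram: the q-quantile is the smallest value whose
#' cumulative count reaches `ceiling(q * depth)` — exact for integer Phred
#' data. Composition fractions use the full position depth (including `N`)
#' as denominator, so they sum to 1. All ratios are reported as 0 with
#' `zero_depth = TRUE` when there is no data.
#'
#' @param stats a `dataset_stats` object.
#' @return A `qc_summary` list with elements `overall` (named list) and
#'   `per_position` (list of one data frame per mate, one row per 1-based
#'   cycle).
#' @export
summarize_stats <- function(stats) {
  zero <- stats$n_bases == 0
  overall <- list(
    n_records = stats$n_records,
    n_reads = stats$n_reads,
    n_bases = stats$n_bases,
    q20 = if (zero) 0 else stats$q20_bases / stats$n_bases,
    q30 = if (zero) 0 else stats$q30_bases / stats$n_bases,
    gc = if (zero) 0 else
      unname((stats$base_totals["G"] + stats$base_totals["C"]) / stats$n_bases),
    base_totals = as.list(stats$base_totals),
    zero_depth = zero
  )
  per_position <- lapply(stats$pos, function(ps) {
    L <- ncol(ps$base_counts)
    if (L == 0L) {
      return(data.frame(position = integer(), depth = numeric(),
                        A = numeric(), C = numeric(), G = numeric(),
                        T = numeric(), N = numeric(),
                        frac_A = numeric(), frac_C = numeric(),
                        frac_G = numeric(), frac_T = numeric(),
                        frac_N = numeric(), q20 = numeric(), q30 = numeric(),
                        mean_qual = numeric(), min = numeric(),
                        q1 = numeric(), median = numeric(), q3 = numeric(),
                        max = numeric()))
    }
    depth <- colSums(ps$base_counts)
    fr <- sweep(ps$base_counts, 2, pmax(depth, 1), "/")
    qh <- ps$qual_hist
    vals <- 0:MAX_PHRED
    qdepth <- colSums(qh)
    q20p <- colSums(qh[vals >= 20, , drop = FALSE]) / pmax(qdepth, 1)
    q30p <- colSums(qh[vals >= 30, , drop = FALSE]) / pmax(qdepth, 1)
    meanq <- colSums(qh * vals) / pmax(qdepth, 1)
    quant <- function(p) {
      vapply(seq_len(L), function(j) hist_quantile(qh[, j], p), numeric(1))
    }
    mn <- vapply(seq_len(L), function(j) {
      nz <- which(qh[, j] > 0)
      if (length(nz)) vals[nz[1]] else NA_real_
    }, numeric(1))
    mx <- vapply(seq_len(L), function(j) {
      nz <- which(qh[, j] > 0)
      if (length(nz)) vals[nz[length(nz)]] else NA_real_
    }, numeric(1))
    data.frame(position = seq_len(L), depth = depth,
               A = ps$base_counts["A", ], C = ps$base_counts["C", ],
               G = ps$base_counts["G", ], T = ps$base_counts["T", ],
               N = ps$base_counts["N", ],
               frac_A = fr["A", ], frac_C = fr["C", ], frac_G = fr["G", ],
               frac_T = fr["T", ], frac_N = fr["N", ],
               q20 = q20p, q30 = q30p, mean_qual = meanq,
               min = mn, q1 = quant(0.25), median = quant(0.5),
               q3 = quant(0.75), max = mx, row.names = NULL)
  })
  structure(list(overall = overall, per_position = per_position,
                 paired = stats$paired),
            class = "qc_summary")
}

QC_MEDIAN_FAIL <- 20
QC_MEDIAN_WARN <- 25
QC_COMPOSITION_FAIL <- 20
QC_COMPOSITION_WARN <- 10

#' Evaluate warn/fail thresholds on a QC summary of preprocessed data
#'
#' Two checks, applied at every nonzero-depth position of every mate:
#'
#' * per-base quality: a position whose median Phred score is below 20 is a
#'   failure; below 25 (but not below 20) is a warning.
#' * base composition: a position where the A and T percentages (or the G
#'   and C percentages, relative to the full depth including `N`) differ by
#'   more than 20 percentage points is a failure; more than 10 a warning.
#'
#' Values exactly at a threshold do not trigger (strict inequalities).
#' The verdict status is `"fail"` if any fail-level finding exists,
#' `"warn"` if only warn-level findings exist, else `"pass"`.
#'
#' @param summary a `qc_summary` from [summarize_stats()], computed on the
#'   preprocessed (clean) data.
#' @return A `qc_verdict`: list with `status` and a `findings` data frame
#'   (check, mate, position, observed, threshold, level).
#' @export
evaluate_thresholds <- function(summary) {
  findings <- list()
  add <- function(check, mate, pos, obs, thr, level) {
    findings[[length(findings) + 1L]] <<- data.frame(
      check = check, mate = mate, position = pos, observed = obs,
      threshold = thr, level = level)
  }
  for (m in seq_along(summary$per_position)) {
    tab <- summary$per_position[[m]]
    tab <- tab[tab$depth > 0, , drop = FALSE]
    if (nrow(tab) == 0L) next
    fail <- tab$median < QC_MEDIAN_FAIL
    warn <- !fail & tab$median < QC_MEDIAN_WARN
    if (any(fail)) add("base_quality_median", m, tab$position[fail],
                       tab$median[fail], QC_MEDIAN_FAIL, "fail")
    if (any(warn)) add("base_quality_median", m, tab$position[warn],
                       tab$median[warn], QC_MEDIAN_WARN, "warn")
    # from integer counts: a single correctly-rounded division keeps values
    # that are exactly at a threshold exactly representable
    diff_at <- abs(tab$A - tab$T) * 100 / tab$depth
    diff_gc <- abs(tab$G - tab$C) * 100 / tab$depth
    comp <- pmax(diff_at, diff_gc)
    fail <- comp > QC_COMPOSITION_FAIL
    warn <- !fail & comp > QC_COMPOSITION_WARN
    if (any(fail)) add("base_composition", m, tab$position[fail],
                       comp[fail], QC_COMPOSITION_FAIL, "fail")
    if (any(warn)) add("base_composition", m, tab$position[warn],
                       comp[warn], QC_COMPOSITION_WARN, "warn")
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(check = character(), mate = integer(), position = integer(),
               observed = numeric(), threshold = numeric(),
               level = character())
  status <- if (any(findings$level == "fail")) "fail"
            else if (any(findings$level == "warn")) "warn" else "pass"
  structure(list(status = status, findings = findings), class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s (%d finding(s))\n", x$status, nrow(x$findings)))
  if (nrow(x$findings)) print(utils::head(x$findings, 10))
  invisible(x)
}

#' Write the QC report file set
#'
#' Emits one machine-readable `summary.json` (raw vs clean counts, Q20/Q30,
#' GC, the per-reason filter tally and the threshold verdict) plus four
#' per-position TSV tables per mate: the full quality-value histogram
#' (`base_quality*.txt`), the five-number quality summary
#' (`qual_boxplot*.txt`), per-position Q20/Q30 (`q20q30_by_pos*.txt`) and
#' base composition (`base_composition*.txt`). Tables carry per-mate
#' suffixes `_1`/`_2` for paired data, one row per 1-based cycle.
#'
#' @param raw `dataset_stats` of the raw input.
#' @param clean `dataset_stats` of the preprocessed output (its
#'   `filter_tally` holds the per-reason drop counts).
#' @param verdict a `qc_verdict` from [evaluate_thresholds()].
#' @param out_dir output directory (created if needed).
#' @param plots also render simple line/box plots of the per-position tables
#'   as PNG files.
#' @return Invisibly, the character vector of files written.
#' @export
write_qc_report <- function(raw, clean, verdict, out_dir, plots = FALSE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  raw_s <- summarize_stats(raw)
  clean_s <- summarize_stats(clean)
  files <- character()
  doc <- list(
    tool = "cleanfq",
    version = as.character(utils::packageVersion("cleanfq")),
    raw = raw_s$overall,
    clean = clean_s$overall,
    filter_tally = as.list(clean$filter_tally),
    verdict = list(status = verdict$status, findings = verdict$findings)
  )
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  mates <- seq_along(clean_s$per_position)
  for (m in mates) {
    sfx <- if (clean$paired) paste0("_", m) else ""
    tab <- clean_s$per_position[[m]]
    qh <- t(clean$pos[[m]]$qual_hist)
    keep <- which(colSums(qh) > 0)
    hist_df <- data.frame(position = seq_len(nrow(qh)))
    for (j in keep) hist_df[[paste0("q", j - 1L)]] <- qh[, j]
    write_tsv(hist_df, paste0("base_quality", sfx, ".txt"))
    write_tsv(tab[, c("position", "depth", "min", "q1", "median", "q3",
                      "max", "mean_qual")],
              paste0("qual_boxplot", sfx, ".txt"))
    write_tsv(tab[, c("position", "depth", "q20", "q30")],
              paste0("q20q30_by_pos", sfx, ".txt"))
    write_tsv(tab[, c("position", "depth", "A", "C", "G", "T", "N",
                      "frac_A", "frac_C", "frac_G", "frac_T", "frac_N")],
              paste0("base_composition", sfx, ".txt"))
    if (plots && nrow(tab) > 0) {
      files <- c(files, qc_plot_panels(tab, out_dir, sfx))
    }
  }
  invisible(files)
}

# Minimal per-position panels: quality quantiles and composition fractions.
qc_plot_panels <- function(tab, out_dir, sfx) {
  path <- file.path(out_dir, paste0("qc_panels", sfx, ".png"))
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  graphics::plot(tab$position, tab$median, type = "l", ylim = c(0, 45),
                 xlab = "position (cycle)", ylab = "Phred quality",
                 main = "Per-base quality (median, quartiles)")
  graphics::lines(tab$position, tab$q1, lty = 2)
  graphics::lines(tab$position, tab$q3, lty = 2)
  graphics::abline(h = c(20, 30), col = "grey60")
  graphics::plot(tab$position, tab$frac_A, type = "l", col = "forestgreen",
                 ylim = c(0, 1), xlab = "position (cycle)", ylab = "fraction",
                 main = "Per-base composition")
  graphics::lines(tab$position, tab$frac_C, col = "royalblue")
  graphics::lines(tab$position, tab$frac_G, col = "black")
  graphics::lines(tab$position, tab$frac_T, col = "firebrick")
  graphics::lines(tab$position, tab$frac_N, col = "grey50")
  graphics::legend("topright", legend = c("A", "C", "G", "T", "N"), lwd = 1,
                   col = c("forestgreen", "royalblue", "black", "firebrick",
                           "grey50"))
  path
}
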