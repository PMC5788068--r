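#' Pipeline configuration
#'
#' Bundles every tunable of a preprocessing run. Module-specific defaults:
#'
#' * `general` — the full battery at its documented defaults.
#' * `dge` — single-end tag extraction around an anchor motif (`CATG`, the
#'   NlaIII site) keeping the `dge_tag_len` bases after it; tags with any
#'   ambiguous base are dropped (`max_n_fraction = 0`), and the length
#'   filter is off because every surviving tag has the same length.
#' * `srna` — single-end; 3' adapter removal, poly-A contaminant filter
#'   (`polya_fraction`), and a length window of `min_length`..`max_length`
#'   (default 18..30 nt, mature small-RNA sizes).
#' * `meta` — adapter and quality end-trimming plus length and
#'   ambiguous-base filters only; mean-quality and low-quality-base
#'   filters, deduplication and batch exclusion are off unless explicitly
#'   configured.
#'
#' @param module `"general"`, `"dge"`, `"srna"` or `"meta"`.
#' @param adapter,adapter2 3' adapter for mate 1 / mate 2: a string, a
#'   single-record FASTA path, or an [adapter_spec()]. `adapter2` defaults
#'   to `adapter`.
#' @param trim_head,trim_tail bases trimmed unconditionally from the 5'/3'
#'   ends.
#' @param qual_trim Phred threshold for trimming low-quality bases off both
#'   ends (0 = off).
#' @param filters a [filter_spec()]; omit for the module default.
#' @param transform `"none"`, `"dna_to_rna"` or `"rna_to_dna"`, applied to
#'   the clean output.
#' @param polya_fraction minimum fraction of `A` for a read to count as a
#'   poly-A contaminant (small-RNA module).
#' @param dge_anchor,dge_tag_len,keep_anchor anchor motif, tag length, and
#'   whether the anchor is retained in the output tag (DGE module).
#' @param block_size records per processing block.
#' @param workers worker processes for block processing.
#' @param in_encoding `"auto"`, `"phred33"` or `"phred64"`.
#' @param out_encoding output serialization.
#' @param gzip gzip-compress output FASTQ.
#' @param merge_fastq merge per-block output into integrated FASTQ files
#'   (otherwise per-block files with zero-padded index suffixes are kept).
#' @param plots render simple QC plots alongside the report tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(module = c("general", "dge", "srna", "meta"),
                            adapter = NULL, adapter2 = NULL,
                            trim_head = 0L, trim_tail = 0L, qual_trim = 0L,
                            filters = NULL,
                            transform = c("none", "dna_to_rna", "rna_to_dna"),
                            polya_fraction = 0.7,
                            dge_anchor = "CATG", dge_tag_len = 17L,
                            keep_anchor = FALSE,
                            block_size = 100000L, workers = 1L,
                            in_encoding = "auto", out_encoding = "phred33",
                            gzip = FALSE, merge_fastq = TRUE, plots = FALSE) {
  module <- match.arg(module)
  transform <- match.arg(transform)
  as_adapter <- function(a) {
    if (is.null(a) || inherits(a, "adapter_spec")) a else adapter_spec(a)
  }
  adapter <- as_adapter(adapter)
  adapter2 <- if (is.null(adapter2)) adapter else as_adapter(adapter2)
  if (is.null(filters)) {
    filters <- switch(module,
      general = filter_spec(),
      dge = filter_spec(min_length = 0L, max_n_fraction = 0),
      srna = filter_spec(max_length = 30L),
      meta = filter_spec(min_mean_quality = 0, max_low_qual_fraction = 1))
  }
  stopifnot(dge_tag_len >= 1L, polya_fraction >= 0, polya_fraction <= 1,
            block_size >= 1L, workers >= 1L)
  structure(list(module = module, adapter = adapter, adapter2 = adapter2,
                 trim_head = as.integer(trim_head),
                 trim_tail = as.integer(trim_tail),
                 qual_trim = as.integer(qual_trim), filters = filters,
                 transform = transform, polya_fraction = polya_fraction,
                 dge_anchor = toupper(dge_anchor),
                 dge_tag_len = as.integer(dge_tag_len),
                 keep_anchor = isTRUE(keep_anchor),
                 block_size = as.integer(block_size),
                 workers = as.integer(workers),
                 in_encoding = in_encoding, out_encoding = out_encoding,
                 gzip = isTRUE(gzip), merge_fastq = isTRUE(merge_fastq),
                 plots = isTRUE(plots)),
            class = "pipeline_config")
}

#' Extract the anchored tag from DGE reads
#'
#' Locates the first (leftmost) occurrence of the anchor motif in each read
#' and keeps the `tag_len` bases immediately following it (the anchor itself
#' is excluded unless `keep_anchor`). Reads without the anchor, or with
#' fewer than `tag_len` bases after it, are reported as not found and left
#' unchanged (they are dropped downstream).
#'
#' @param reads an `fq_reads` object (single-end).
#' @param anchor anchor motif (default `"CATG"`).
#' @param tag_len tag length in bases (default 17).
#' @param keep_anchor prepend the anchor to the extracted tag.
#' @return List with `reads` (tags substituted where found) and logical
#'   `found`.
#' @export
find_dge_tag <- function(reads, anchor = "CATG", tag_len = 17L,
                         keep_anchor = FALSE) {
  pos <- regexpr(anchor, toupper(reads$seq), fixed = TRUE)
  start <- ifelse(pos > 0L, pos + nchar(anchor), NA_integer_)
  found <- pos > 0L & (start + tag_len - 1L) <= nchar(reads$seq)
  from <- if (keep_anchor) as.integer(pos) else start
  to <- start + tag_len - 1L
  if (any(found)) {
    reads$seq[found] <- substr(reads$seq[found], from[found], to[found])
    reads$qual[found] <- substr(reads$qual[found], from[found], to[found])
  }
  list(reads = reads, found = found)
}

#' Flag poly-A contaminant reads
#'
#' A read counts as poly-A when its fraction of `A` bases
#' (case-insensitive) is at least `polya_fraction`. Zero-length reads are
#' never poly-A.
#'
#' @param reads an `fq_reads` object.
#' @param polya_fraction threshold fraction (default 0.7).
#' @return Logical vector, one flag per read.
#' @export
is_polya <- function(reads, polya_fraction = 0.7) {
  len <- nchar(reads$seq)
  na <- len - nchar(gsub("[Aa]", "", reads$seq))
  len > 0L & na / len >= polya_fraction
}

# Pure per-block processor: raw stats -> duplicate drop -> trims -> module
# stage -> filter battery -> clean stats. `block$dup` carries the global
# duplicate flags assigned by the streaming pre-pass.
process_block <- function(block, config) {
  paired <- !is.null(block$r2)
  r1 <- block$r1
  r2 <- block$r2
  n <- length(r1)
  raw <- new_dataset_stats(paired)
  raw <- accumulate_stats(raw, r1, 1L)
  if (paired) raw <- accumulate_stats(raw, r2, 2L)
  reason <- rep(NA_character_, n)
  if (!is.null(block$dup)) reason[block$dup] <- "duplicate"

  r1 <- trim_fixed_ends(r1, config$trim_head, config$trim_tail)
  if (paired) r2 <- trim_fixed_ends(r2, config$trim_head, config$trim_tail)

  adapter_found <- rep(FALSE, n)
  if (config$module == "dge") {
    tg <- find_dge_tag(r1, config$dge_anchor, config$dge_tag_len,
                       config$keep_anchor)
    r1 <- tg$reads
    sel <- !tg$found & is.na(reason)
    reason[sel] <- "dge_tag_missing"
  } else {
    if (!is.null(config$adapter)) {
      hits <- align_adapter(r1, config$adapter)
      adapter_found <- !is.na(hits$offset)
      if (!config$filters$drop_adapter_reads) r1 <- trim_adapter(r1, hits)
    }
    if (paired && !is.null(config$adapter2)) {
      hits2 <- align_adapter(r2, config$adapter2)
      adapter_found <- adapter_found | !is.na(hits2$offset)
      if (!config$filters$drop_adapter_reads) r2 <- trim_adapter(r2, hits2)
    }
  }
  if (config$module == "srna") {
    pa <- is_polya(r1, config$polya_fraction)
    sel <- pa & is.na(reason)
    reason[sel] <- "polya"
  }
  if (config$qual_trim > 0L) {
    r1 <- trim_low_quality_ends(r1, config$qual_trim)
    if (paired) r2 <- trim_low_quality_ends(r2, config$qual_trim)
  }
  batch <- NULL
  if (length(config$filters$excluded_batches)) {
    batch <- parse_batch_coordinate(r1$id, config$filters$batch_kind)
  }
  verdict <- apply_filters(r1, r2, config$filters, adapter_found, batch)
  reason <- ifelse(is.na(reason) & !verdict$keep, verdict$reason, reason)
  keep <- is.na(reason)

  r1 <- r1[keep]
  if (paired) r2 <- r2[keep]
  if (config$transform != "none") {
    r1 <- transform_sequence(r1, config$transform)
    if (paired) r2 <- transform_sequence(r2, config$transform)
  }
  clean <- new_dataset_stats(paired)
  clean <- accumulate_stats(clean, r1, 1L)
  if (paired) clean <- accumulate_stats(clean, r2, 2L)
  clean <- tally_filtered(clean, reason[!keep])
  list(index = block$index, r1 = r1, r2 = if (paired) r2 else NULL,
       raw = raw, clean = clean)
}

# Serialize reads to FASTQ lines under the configured output encoding.
format_fastq_lines <- function(reads, encoding) {
  if (length(reads) == 0L) return(character())
  hdr <- paste0("@", reads$id,
                ifelse(nzchar(reads$comment), paste0(" ", reads$comment), ""))
  qual <- serialize_quals(reads, encoding)
  as.vector(rbind(hdr, reads$seq, "+", qual))
}

#' Run a preprocessing pipeline
#'
#' The full two-pass workflow: raw statistics, per-block trimming/filtering
#' in the module's stage order, clean statistics, the warn/fail verdict on
#' the clean data, report files and clean FASTQ output. Input is streamed
#' in blocks of `config$block_size` records; deduplication (when enabled)
#' is a streaming pre-pass with one global key set, so results are
#' independent of block size and worker count. All outputs are staged in a
#' temporary directory and moved into `out_dir` only on success, so a
#' failed run leaves no partial output.
#'
#' @param config a [pipeline_config()].
#' @param in1 path to the (mate-1) FASTQ file, plain or gzip.
#' @param in2 optional mate-2 path for paired-end data.
#' @param out_dir output directory.
#' @return Invisibly, a list with the merged `raw` and `clean`
#'   [new_dataset_stats()] objects, the `verdict`, the output `files`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, in1, in2 = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$module %in% c("dge", "srna") && !is.null(in2)) {
    stop("the ", config$module, " module takes single-end input only")
  }
  paired <- !is.null(in2)
  t_start <- Sys.time()
  st1 <- fastq_stream(in1, config$in_encoding)
  on.exit(close_stream(st1), add = TRUE)
  st2 <- NULL
  if (paired) {
    st2 <- fastq_stream(in2, config$in_encoding)
    on.exit(close_stream(st2), add = TRUE)
  }
  work <- tempfile("cleanfq_work_")
  dir.create(work, recursive = TRUE)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)

  ext <- if (config$gzip) ".fq.gz" else ".fq"
  out_names <- if (paired) paste0("clean_", 1:2, ext) else paste0("clean", ext)
  cons <- NULL
  if (config$merge_fastq) {
    cons <- lapply(file.path(work, out_names), function(p) {
      if (config$gzip) gzfile(p, "wb") else file(p, "wb")
    })
    on.exit(lapply(cons, function(con) try(close(con), silent = TRUE)),
            add = TRUE)
  }
  dstate <- if (config$filters$dedup) dedup_state() else NULL
  raw <- new_dataset_stats(paired)
  clean <- new_dataset_stats(paired)
  block_files <- character()
  index <- 0L
  pending <- list()

  flush_pending <- function() {
    if (length(pending) == 0L) return(invisible())
    results <- process_blocks(pending, function(b) process_block(b, config),
                              config$workers)
    for (res in results) {
      raw <<- merge_stats(raw, res$raw)
      clean <<- merge_stats(clean, res$clean)
      mates <- if (paired) list(res$r1, res$r2) else list(res$r1)
      for (m in seq_along(mates)) {
        lines <- format_fastq_lines(mates[[m]], config$out_encoding)
        if (config$merge_fastq) {
          if (length(lines)) writeLines(lines, cons[[m]], sep = "\n")
        } else {
          stem <- sub("\\.fq(\\.gz)?$", "", out_names[m])
          bf <- file.path(work, sprintf("%s.block%03d%s", stem, res$index, ext))
          bcon <- if (config$gzip) gzfile(bf, "wb") else file(bf, "wb")
          writeLines(lines, bcon, sep = "\n")
          close(bcon)
          block_files <<- c(block_files, bf)
        }
      }
    }
    pending <<- list()
    invisible()
  }

  repeat {
    b1 <- read_block(st1, config$block_size)
    b2 <- if (paired) read_block(st2, config$block_size) else NULL
    if (is.null(b1) || (paired && is.null(b2))) {
      if (!is.null(b1) || (paired && !is.null(b2))) {
        stop("paired files desynchronized: one input ended at record ",
             st1$ordinal + 1L)
      }
      break
    }
    if (paired) {
      if (length(b1) != length(b2)) {
        stop("paired files desynchronized near record ",
             st1$ordinal - length(b1) + min(length(b1), length(b2)) + 1L)
      }
      id1 <- strip_mate_suffix(b1$id)
      id2 <- strip_mate_suffix(b2$id)
      bad <- which(id1 != id2)
      if (length(bad)) {
        ord <- st1$ordinal - length(b1) + bad[1]
        stop("paired files desynchronized at record ", ord, ": '",
             b1$id[bad[1]], "' vs '", b2$id[bad[1]], "'")
      }
    }
    dup <- NULL
    if (!is.null(dstate)) {
      dup <- mark_duplicates(dedup_key(b1, b2), dstate)
    }
    pending[[length(pending) + 1L]] <- list(index = index, r1 = b1, r2 = b2,
                                            dup = dup)
    index <- index + 1L
    if (length(pending) >= config$workers) flush_pending()
  }
  flush_pending()
  if (config$merge_fastq) {
    lapply(cons, close)
    cons <- NULL
  }

  clean_sum <- summarize_stats(clean)
  verdict <- evaluate_thresholds(clean_sum)
  files <- write_qc_report(raw, clean, verdict, work, plots = config$plots)
  manifest <- list(
    tool = "cleanfq",
    version = as.character(utils::packageVersion("cleanfq")),
    module = config$module,
    config = manifest_config(config),
    inputs = as.list(tools::md5sum(c(in1, if (paired) in2))),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    verdict = verdict$status
  )
  jsonlite::write_json(manifest, file.path(work, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  staged <- list.files(work, full.names = TRUE)
  ok <- file.copy(staged, out_dir, overwrite = TRUE)
  if (!all(ok)) stop("failed to move outputs into ", out_dir)
  invisible(list(out_dir = out_dir, raw = raw, clean = clean,
                 summary = clean_sum, verdict = verdict,
                 files = file.path(out_dir, basename(staged))))
}

# JSON-safe echo of the configuration (Inf is not valid JSON).
manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$filters <- unclass(cfg$filters)
  if (is.infinite(cfg$filters$max_length)) cfg$filters$max_length <- "Inf"
  for (a in c("adapter", "adapter2")) if (!is.null(cfg[[a]])) {
    cfg[[a]] <- unclass(cfg[[a]])
  }
  cfg
}

#' Module-specific pipeline runners
#'
#' Thin wrappers over [run_pipeline()] fixing the module. `run_general` and
#' `run_meta` accept single- or paired-end input; `run_dge` and `run_srna`
#' are single-end.
#'
#' @param in1,in2 input FASTQ path(s).
#' @param out_dir output directory.
#' @param config a [pipeline_config()] (its module is overridden); omit for
#'   module defaults.
#' @param ... arguments forwarded to [pipeline_config()] when `config` is
#'   not given.
#' @return See [run_pipeline()].
#' @export
run_general <- function(in1, in2 = NULL, out_dir, config = NULL, ...) {
  run_module("general", in1, in2, out_dir, config, ...)
}

#' @rdname run_general
#' @export
run_dge <- function(in1, out_dir, config = NULL, ...) {
  run_module("dge", in1, NULL, out_dir, config, ...)
}

#' @rdname run_general
#' @export
run_srna <- function(in1, out_dir, config = NULL, ...) {
  run_module("srna", in1, NULL, out_dir, config, ...)
}

#' @rdname run_general
#' @export
run_meta <- function(in1, in2 = NULL, out_dir, config = NULL, ...) {
  run_module("meta", in1, in2, out_dir, config, ...)
}

run_module <- function(module, in1, in2, out_dir, config, ...) {
  if (is.null(config)) {
    config <- pipeline_config(module = module, ...)
  } else {
    config$module <- module
  }
  run_pipeline(config, in1, in2, out_dir)
}
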