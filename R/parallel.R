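#' Split reads into fixed-size blocks
#'
#' Every block except possibly the last holds exactly `block_size` records;
#' indices are consecutive from 0 and concatenating the blocks restores the
#' input order. Paired records are never split across blocks.
#'
#' @param r1 an `fq_reads` object (mate 1 or single-end).
#' @param block_size records per block (>= 1).
#' @param r2 optional mate-2 `fq_reads`, parallel to `r1`.
#' @return List of blocks; each block is a list with `index` (0-based),
#'   `r1`, and `r2` (`NULL` for single-end).
#' @export
split_into_blocks <- function(r1, block_size, r2 = NULL) {
  stopifnot(block_size >= 1)
  n <- length(r1)
  if (!is.null(r2) && length(r2) != n) {
    stop("mate files hold different record counts (", n, " vs ", length(r2), ")")
  }
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = block_size)
  lapply(seq_along(starts), function(k) {
    i <- seq.int(starts[k], min(starts[k] + block_size - 1L, n))
    list(index = k - 1L, r1 = r1[i], r2 = if (is.null(r2)) NULL else r2[i])
  })
}

#' Process blocks independently, optionally on multiple workers
#'
#' `stage_fn` must be a pure function of a single block (plus whatever
#' configuration it closes over), so the combined output is a function of
#' the input and configuration only — identical for any worker count and
#' any completion order. Results are always returned in block-index order.
#'
#' @param blocks list of blocks from [split_into_blocks()].
#' @param stage_fn function taking one block and returning its result; the
#'   result must carry the block's `index`.
#' @param workers number of worker processes (forked; values above 1 are
#'   honored on Unix-alikes and fall back to serial elsewhere).
#' @return List of block results, ordered by index. A failure in any block
#'   raises an error naming the block.
#' @export
process_blocks <- function(blocks, stage_fn, workers = 1L) {
  if (length(blocks) == 0L) return(list())
  wrapped <- function(b) {
    tryCatch(list(ok = TRUE, value = stage_fn(b)),
             error = function(e) list(ok = FALSE, index = b$index,
                                      message = conditionMessage(e)))
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(blocks, wrapped, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(blocks, wrapped)
  }
  for (r in res) {
    if (inherits(r, "try-error") || !isTRUE(r$ok)) {
      idx <- if (is.list(r)) r$index else NA
      msg <- if (is.list(r)) r$message else as.character(r)
      stop("processing failed in block ", idx, ": ", msg)
    }
  }
  out <- lapply(res, `[[`, "value")
  out[order(vapply(out, `[[`, integer(1), "index"))]
}

#' Merge block results into whole-run statistics and reads
#'
#' Statistics deltas are combined with [merge_stats()]; kept reads are
#' concatenated in ascending block index, restoring global input order.
#'
#' @param results list of block results (each with `index`, `r1`,
#'   optionally `r2`, `raw`, `clean`), as produced by the pipeline block
#'   processor.
#' @return List with merged `raw` and `clean` statistics and the
#'   concatenated kept reads `r1` (and `r2` when paired).
#' @export
merge_results <- function(results) {
  if (length(results) == 0L) stop("no block results to merge")
  idx <- vapply(results, `[[`, integer(1), "index")
  if (!identical(sort(idx), seq_along(idx) - 1L)) {
    stop("incomplete block results: indices ", paste(sort(idx), collapse = ","))
  }
  results <- results[order(idx)]
  raw <- Reduce(merge_stats, lapply(results, `[[`, "raw"))
  clean <- Reduce(merge_stats, lapply(results, `[[`, "clean"))
  r1 <- do.call(c, lapply(results, `[[`, "r1"))
  r2s <- lapply(results, `[[`, "r2")
  r2 <- if (is.null(r2s[[1]])) NULL else do.call(c, r2s)
  list(raw = raw, clean = clean, r1 = r1, r2 = r2)
}
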