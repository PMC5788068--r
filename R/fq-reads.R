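#' Vectorized container for FASTQ records
#'
#' `fq_reads` holds a set of sequencing reads as parallel character vectors:
#' read identifier (up to the first whitespace of the header), the remaining
#' header comment, the base string, and the quality string. Quality strings
#' are always stored in canonical Phred+33 serialization regardless of the
#' encoding of the source file; the source encoding is retained as an
#' attribute so it can be reported and restored on output. This makes every
#' trimming operation a pair of parallel `substr()` calls and keeps numeric
#' decoding (`qual_ints()`) a single `utf8ToInt()` per read.
#'
#' @param id character vector of read names (no leading `@`).
#' @param seq character vector of base strings over `A,C,G,T,N` (and `U`
#'   after an RNA transform), case-insensitive.
#' @param qual quality values: either a character vector of Phred+33 strings
#'   or a list of non-negative integer vectors (each in `[0, 93]`).
#' @param comment character vector of header remainders (defaults to empty).
#' @param source_encoding `"phred33"` or `"phred64"`; provenance only, the
#'   stored serialization is always Phred+33.
#' @return An `fq_reads` object.
#' @examples
#' r <- fq_reads("r1", "ACGT", list(c(40L, 40L, 40L, 40L)))
#' qual_ints(r)[[1]]
#' @export
fq_reads <- function(id, seq, qual, comment = NULL,
                     source_encoding = "phred33") {
  id <- as.character(id)
  seq <- as.character(seq)
  if (is.list(qual)) qual <- vapply(qual, encode_phred33, character(1))
  qual <- as.character(qual)
  if (is.null(comment)) comment <- character(length(id))
  stopifnot(length(seq) == length(id), length(qual) == length(id),
            length(comment) == length(id))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch for read(s) at ordinal(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(id = id, comment = comment, seq = seq, qual = qual),
            source_encoding = match.arg(source_encoding,
                                        c("phred33", "phred64")),
            class = "fq_reads")
}

encode_phred33 <- function(q) {
  if (length(q) == 0) return("")
  q <- as.integer(q)
  if (any(q < 0L | q > 93L)) stop("Phred values must be in [0, 93]")
  intToUtf8(q + 33L)
}

#' @export
length.fq_reads <- function(x) length(x$id)

#' @export
`[.fq_reads` <- function(x, i) {
  structure(list(id = x$id[i], comment = x$comment[i],
                 seq = x$seq[i], qual = x$qual[i]),
            source_encoding = attr(x, "source_encoding"),
            class = "fq_reads")
}

#' @export
c.fq_reads <- function(...) {
  xs <- list(...)
  structure(list(id = unlist(lapply(xs, `[[`, "id"), use.names = FALSE),
                 comment = unlist(lapply(xs, `[[`, "comment"), use.names = FALSE),
                 seq = unlist(lapply(xs, `[[`, "seq"), use.names = FALSE),
                 qual = unlist(lapply(xs, `[[`, "qual"), use.names = FALSE)),
            source_encoding = attr(xs[[1]], "source_encoding"),
            class = "fq_reads")
}

#' @export
print.fq_reads <- function(x, ...) {
  cat(sprintf("<fq_reads> %d record(s), source encoding %s\n",
              length(x), attr(x, "source_encoding")))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  @%s  %s  [%s]\n", x$id[i],
                abbrev_str(x$seq[i]), abbrev_str(x$qual[i])))
  }
  if (length(x) > n) cat(sprintf("  ... %d more\n", length(x) - n))
  invisible(x)
}

abbrev_str <- function(s, w = 40L) {
  ifelse(nchar(s) > w, paste0(substr(s, 1, w - 3), "..."), s)
}

#' Decode quality strings to integer Phred scores
#'
#' @param x an `fq_reads` object.
#' @return A list of integer vectors, one per read, each value in `[0, 93]`.
#' @export
qual_ints <- function(x) {
  lapply(x$qual, function(s) if (nzchar(s)) utf8ToInt(s) - 33L else integer())
}

#' Read lengths of an `fq_reads` object
#' @param x an `fq_reads` object.
#' @return Integer vector of sequence lengths.
#' @export
read_lengths <- function(x) nchar(x$seq)

#' Strip a trailing mate suffix ("/1" or "/2") from read identifiers
#' @param id character vector of read names.
#' @return Names with any trailing `/1` or `/2` removed.
#' @export
strip_mate_suffix <- function(id) sub("/[12]$", "", id)

empty_fq <- function(source_encoding = "phred33") {
  fq_reads(character(), character(), character(),
           source_encoding = source_encoding)
}
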