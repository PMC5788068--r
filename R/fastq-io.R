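#' Quality encodings
#'
#' FASTQ serializes Phred scores as ASCII characters at an offset of 33
#' (Sanger/Illumina 1.8+) or 64 (Illumina 1.3--1.7). Decoded values are the
#' offset subtracted from the character code and must be non-negative.
#'
#' @param name `"phred33"` or `"phred64"`.
#' @return A list with `name` and integer `offset`.
#' @export
quality_encoding <- function(name = c("phred33", "phred64")) {
  name <- match.arg(name)
  list(name = name, offset = if (name == "phred33") 33L else 64L)
}

#' Detect the quality encoding of raw FASTQ quality strings
#'
#' Decision rule: any character below ASCII 59 is impossible under Phred+64
#' (it would decode below zero), so the sample is Phred+33. If every
#' character is at ASCII 64 or above and at least one exceeds 74 (Phred+33
#' score > 41, which real Phred+33 data does not reach), the sample is
#' Phred+64. Otherwise the two encodings cannot be distinguished and the
#' configured default is returned with `ambiguous = TRUE`.
#'
#' @param qual_strings character vector of raw (undecoded) quality strings.
#' @param default encoding name assumed when the sample is ambiguous.
#' @return List with `encoding` (see [quality_encoding()]) and logical
#'   `ambiguous`.
#' @export
detect_quality_encoding <- function(qual_strings, default = "phred33") {
  qual_strings <- qual_strings[nzchar(qual_strings)]
  if (length(qual_strings) == 0) stop("no records to detect encoding from")
  codes <- utf8ToInt(paste(qual_strings, collapse = ""))
  if (any(codes < 59L)) {
    list(encoding = quality_encoding("phred33"), ambiguous = FALSE)
  } else if (all(codes >= 64L) && any(codes > 74L)) {
    list(encoding = quality_encoding("phred64"), ambiguous = FALSE)
  } else {
    list(encoding = quality_encoding(default), ambiguous = TRUE)
  }
}

# Shift a vector of quality strings between ASCII offsets in one chartr call.
shift_qual_serialization <- function(qual, from_offset, to_offset) {
  if (from_offset == to_offset) return(qual)
  lo <- from_offset
  hi <- from_offset + 93L
  hi <- min(hi, 126L + from_offset - to_offset, 126L)
  chartr(intToUtf8(lo:hi), intToUtf8((lo:hi) - from_offset + to_offset), qual)
}

#' Open a streaming FASTQ reader
#'
#' Reads 4-line FASTQ records from a plain or gzip-compressed file (gzip is
#' detected from the leading magic bytes, not the file name) in blocks, so a
#' file is never resident in memory as a whole. Quality characters are
#' decoded with the given or auto-detected encoding and re-serialized to the
#' canonical internal Phred+33 form.
#'
#' @param path path to a FASTQ file, optionally gzip-compressed.
#' @param encoding `"auto"`, `"phred33"` or `"phred64"`. With `"auto"` the
#'   first `detect_n` records are inspected (see
#'   [detect_quality_encoding()]).
#' @param detect_n number of records sampled for auto-detection.
#' @return A `fastq_stream` object; pass it to [read_block()] repeatedly and
#'   [close_stream()] when done.
#' @seealso [read_fastq()] for whole-file reading.
#' @export
fastq_stream <- function(path, encoding = "auto", detect_n = 10000L) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- gzfile(path, "rt")  # reads plain files transparently
  st <- new.env(parent = emptyenv())
  st$con <- con
  st$path <- path
  st$ordinal <- 0L      # records already delivered
  st$buffer <- NULL     # parsed fq_reads waiting to be delivered
  st$eof <- FALSE
  st$ambiguous <- FALSE
  if (identical(encoding, "auto")) {
    lines <- readLines(con, n = detect_n * 4L)
    recs <- split_fastq_lines(lines, 0L, at_eof = length(lines) < detect_n * 4L)
    if (length(recs$qual) == 0) {
      st$encoding <- quality_encoding("phred33")
      st$eof <- TRUE
    } else {
      det <- detect_quality_encoding(recs$qual)
      st$encoding <- det$encoding
      st$ambiguous <- det$ambiguous
      if (det$ambiguous) {
        warning("quality encoding ambiguous for ", path,
                "; assuming ", st$encoding$name)
      }
      st$buffer <- finish_records(recs, st$encoding$offset)
      st$eof <- length(lines) < detect_n * 4L
    }
  } else {
    st$encoding <- quality_encoding(encoding)
  }
  class(st) <- "fastq_stream"
  st
}

#' @export
print.fastq_stream <- function(x, ...) {
  cat(sprintf("<fastq_stream> %s (%s), %d record(s) delivered\n",
              x$path, x$encoding$name, x$ordinal))
  invisible(x)
}

#' Read the next block of records from a stream
#'
#' @param stream a [fastq_stream()].
#' @param n maximum number of records to return.
#' @return An `fq_reads` object with up to `n` records, or `NULL` at
#'   end of file.
#' @export
read_block <- function(stream, n) {
  out <- NULL
  if (!is.null(stream$buffer)) {
    buf <- stream$buffer
    if (length(buf) > n) {
      out <- buf[seq_len(n)]
      stream$buffer <- buf[seq.int(n + 1L, length(buf))]
      stream$ordinal <- stream$ordinal + length(out)
      return(out)
    }
    out <- buf
    stream$buffer <- NULL
  }
  need <- n - if (is.null(out)) 0L else length(out)
  if (need > 0L && !stream$eof) {
    lines <- readLines(stream$con, n = need * 4L)
    if (length(lines) < need * 4L) stream$eof <- TRUE
    if (length(lines) > 0L) {
      already <- stream$ordinal + if (is.null(out)) 0L else length(out)
      recs <- split_fastq_lines(lines, already, at_eof = stream$eof)
      fresh <- finish_records(recs, stream$encoding$offset)
      out <- if (is.null(out)) fresh else c(out, fresh)
    }
  }
  if (is.null(out) || length(out) == 0L) return(NULL)
  stream$ordinal <- stream$ordinal + length(out)
  out
}

#' Close a FASTQ stream
#' @param stream a [fastq_stream()].
#' @return Invisibly, `NULL`.
#' @export
close_stream <- function(stream) {
  try(close(stream$con), silent = TRUE)
  invisible(NULL)
}

# Validate 4-line structure and split into header/seq/qual vectors.
# `delivered` is the number of records before this batch (for error ordinals).
split_fastq_lines <- function(lines, delivered, at_eof) {
  nl <- length(lines)
  if (nl == 0L) return(list(id = character(), comment = character(),
                            seq = character(), qual = character()))
  if (at_eof && nl %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record at record %d (%d dangling line(s))",
                 delivered + nl %/% 4L + 1L, nl %% 4L))
  }
  idx <- seq.int(1L, nl, by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record at record %d: missing '@' or '+' line",
                 delivered + bad[1]))
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf(
      "sequence and quality lengths differ at record %d (%d vs %d)",
      delivered + bad[1], nchar(seq[bad[1]]), nchar(qual[bad[1]])))
  }
  sp <- regexpr("[ \t]", hdr)
  id <- ifelse(sp > 0L, substr(hdr, 2L, sp - 1L), substr(hdr, 2L, nchar(hdr)))
  comment <- ifelse(sp > 0L, substr(hdr, sp + 1L, nchar(hdr)), "")
  list(id = id, comment = comment, seq = seq, qual = qual)
}

finish_records <- function(recs, offset) {
  if (length(recs$qual)) {
    codes <- utf8ToInt(paste(recs$qual, collapse = ""))
    if (any(codes < offset)) {
      stop("negative quality value decoded; wrong encoding offset ", offset, "?")
    }
  }
  qual33 <- shift_qual_serialization(recs$qual, offset, 33L)
  fq_reads(recs$id, recs$seq, qual33, recs$comment,
           source_encoding = if (offset == 33L) "phred33" else "phred64")
}

#' Read an entire FASTQ file
#'
#' Convenience wrapper over [fastq_stream()] for files that fit in memory.
#'
#' @inheritParams fastq_stream
#' @return An `fq_reads` object; attribute `encoding_ambiguous` is `TRUE`
#'   when auto-detection had to fall back to the default.
#' @export
read_fastq <- function(path, encoding = "auto") {
  st <- fastq_stream(path, encoding)
  on.exit(close_stream(st))
  out <- empty_fq(st$encoding$name)
  repeat {
    blk <- read_block(st, 100000L)
    if (is.null(blk)) break
    out <- c(out, blk)
  }
  attr(out, "encoding_ambiguous") <- st$ambiguous
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads an `fq_reads` object.
#' @param path output path; a name ending in `.gz` forces gzip compression.
#' @param encoding target serialization, `"phred33"` or `"phred64"`.
#' @param gzip force (`TRUE`) or suppress (`FALSE`) gzip output; default
#'   follows the file extension.
#' @param append append to an existing file instead of overwriting.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(reads, path, encoding = "phred33", gzip = NULL,
                        append = FALSE) {
  enc <- quality_encoding(encoding)
  if (is.null(gzip)) gzip <- grepl("\\.gz$", path)
  if (enc$offset != 33L && length(reads)) {
    qmax <- vapply(qual_ints(reads), function(q) {
      if (length(q)) max(q) else 0L
    }, integer(1))
    bad <- which(qmax + enc$offset > 126L)
    if (length(bad)) {
      stop("quality value ", qmax[bad[1]], " of read '", reads$id[bad[1]],
           "' is not representable under ", encoding)
    }
  }
  mode <- if (append) "ab" else "wb"
  con <- if (gzip) gzfile(path, mode) else file(path, mode)
  on.exit(close(con))
  if (length(reads)) {
    hdr <- paste0("@", reads$id,
                  ifelse(nzchar(reads$comment), paste0(" ", reads$comment), ""))
    qual <- shift_qual_serialization(reads$qual, 33L, enc$offset)
    txt <- paste(hdr, reads$seq, "+", qual, sep = "\n")
    writeLines(txt, con, sep = "\n")
  }
  invisible(length(reads))
}

#' Convert a read set to another quality encoding
#'
#' Numeric Phred values never change; only the recorded source encoding (and
#' therefore the characters used when the reads are serialized) does.
#' Converting back restores the original serialization exactly.
#'
#' @param reads an `fq_reads` object.
#' @param target `"phred33"` or `"phred64"`.
#' @return The same reads tagged with the target encoding.
#' @export
convert_quality_encoding <- function(reads, target = c("phred33", "phred64")) {
  target <- match.arg(target)
  attr(reads, "source_encoding") <- target
  reads
}

#' Serialize the quality values of a read under a given encoding
#'
#' @param reads an `fq_reads` object.
#' @param encoding `"phred33"` or `"phred64"`.
#' @return Character vector of serialized quality strings.
#' @export
serialize_quals <- function(reads, encoding = c("phred33", "phred64")) {
  enc <- quality_encoding(match.arg(encoding))
  shift_qual_serialization(reads$qual, 33L, enc$offset)
}

#' Extract sequencing-batch coordinates from read names
#'
#' Illumina flowcell tiles are taken from the 5th colon-delimited field of
#' the read name (CASAVA >= 1.8 convention); BGI fields of view (fov) are the
#' first substring matching `C<3 digits>R<3 digits>` anywhere in the name
#' (fixed-width column/row labels, so trailing coordinate digits in the name
#' are not swallowed).
#'
#' @param id character vector of read names.
#' @param kind `"tile"` or `"fov"`.
#' @return Character vector of batch labels, `NA` where the pattern is
#'   absent.
#' @examples
#' parse_batch_coordinate("EAS139:136:FC706VJ:2:2104:15343:197393", "tile")
#' @export
parse_batch_coordinate <- function(id, kind = c("tile", "fov")) {
  kind <- match.arg(kind)
  if (kind == "tile") {
    parts <- strsplit(id, ":", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) >= 5L && grepl("^[0-9]+$", p[5])) p[5] else NA_character_
    }, character(1))
  } else {
    hit <- regexpr("C[0-9]{3}R[0-9]{3}", id)
    out <- rep(NA_character_, length(id))
    out[hit > 0L] <- regmatches(id, hit)
    out
  }
}

#' Read an adapter sequence from a string or single-record FASTA file
#'
#' @param x a literal base string, or the path of a single-record FASTA
#'   file.
#' @return The adapter sequence as an upper-case string.
#' @export
adapter_sequence <- function(x) {
  if (file.exists(x)) {
    lines <- readLines(x)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L || substr(lines[1], 1, 1) != ">") {
      stop("adapter FASTA must hold one '>'-headed record: ", x)
    }
    x <- paste(lines[-1], collapse = "")
  }
  x <- toupper(trimws(x))
  if (!grepl("^[ACGT]+$", x)) stop("adapter must be a non-empty ACGT string")
  x
}
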