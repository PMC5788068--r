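# Independent oracles and small builders used across the suite.

# Naive O(n*m) ungapped adapter scorer, independent of the package's C++
# scanner: scans every offset, counts mismatches vectorized on integer
# codes, applies the same validity rule and tie-breaks.
oracle_align <- function(seq, adapter, rate = 0.1, min_overlap = 6L) {
  s <- utf8ToInt(toupper(seq))
  a <- utf8ToInt(toupper(adapter))
  n <- length(s)
  m <- length(a)
  if (n < min_overlap) return(NULL)
  ncode <- utf8ToInt("N")
  best <- NULL
  for (o in 0:(n - min_overlap)) {
    cols <- min(m, n - o)
    seg <- s[(o + 1):(o + cols)]
    mm <- sum(seg != a[seq_len(cols)] | seg == ncode)
    if (mm <= floor(rate * cols)) {
      if (is.null(best) || mm * best$len < best$mm * cols) {
        best <- list(off = o, len = cols, mm = mm)
      }
    }
  }
  best
}

# Sort-based type-1 (inverted-CDF) quantile oracle.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

# Quick single-read builder.
one_read <- function(seq, quals = rep(30L, nchar(seq)), id = "r1") {
  fq_reads(id, seq, list(as.integer(quals)))
}

random_read_set <- function(n, len = 40L, seed = 1L) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = "")
    }, character(1))
    quals <- lapply(seq_len(n), function(i) {
      sample(0:41, len, replace = TRUE)
    })
    fq_reads(sprintf("rr%04d", seq_len(n)), seqs, quals)
  })
}

stats_of <- function(reads) accumulate_stats(new_dataset_stats(), reads)
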