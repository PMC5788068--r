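test_that("adapter alignment finds planted adapters and respects the budget", {
  ad <- adapter_spec("AGATCGGAAGAGC", 0.1, 6L)
  r <- one_read("ACGTACGTAGATCGGAAGAGC")
  h <- align_adapter(r, ad)
  expect_equal(h$offset, 8L)
  expect_equal(h$aligned_len, 13L)
  expect_equal(h$mismatches, 0L)
  expect_equal(trim_adapter(r, h)$seq, "ACGTACGT")
  # no shared 6-mer -> no hit
  expect_true(is.na(align_adapter(one_read("CCCCCCCCCCCCCCCC"), ad)$offset))
  # one substitution within floor(0.1 * 13) = 1
  r1 <- one_read("AGATCGGAACAGC")
  h1 <- align_adapter(r1, ad)
  expect_equal(h1$offset, 0L)
  expect_equal(h1$mismatches, 1L)
  # two substitutions exceed the budget
  expect_true(is.na(align_adapter(one_read("AGATCGGAACAGG"), ad)$offset))
  # hit at offset 0 trims to a zero-length read
  expect_equal(nchar(trim_adapter(r1, h1)$seq), 0L)
})

test_that("adapter scan agrees with the exhaustive oracle on random cases", {
  withr::with_seed(101, {
    n_cases <- 400
    for (i in seq_len(n_cases)) {
      alen <- sample(8:16, 1)
      adapter <- paste(sample(c("A", "C", "G", "T"), alen, TRUE),
                       collapse = "")
      rlen <- sample(15:60, 1)
      seq <- paste(sample(c("A", "C", "G", "T", "N"), rlen, TRUE,
                          prob = c(.245, .245, .245, .245, .02)),
                   collapse = "")
      if (i %% 2 == 0) {  # plant, possibly overhanging, with mutations
        off <- sample(0:(rlen - 6), 1)
        span <- seq.int(off + 1, min(rlen, off + alen))
        achars <- strsplit(adapter, "")[[1]][seq_along(span)]
        if (i %% 4 == 0 && length(span) > 2) {
          k <- sample(seq_along(span), 1)
          achars[k] <- setdiff(c("A", "C", "G", "T"), achars[k])[1]
        }
        substr(seq, off + 1, max(span)) <- paste(achars, collapse = "")
      }
      spec <- adapter_spec(adapter, 0.1, 6L)
      got <- align_adapter(one_read(seq), spec)
      want <- oracle_align(seq, adapter, 0.1, 6L)
      if (is.null(want)) {
        expect_true(is.na(got$offset), label = paste("case", i, seq, adapter))
      } else {
        expect_equal(got$offset, want$off, label = paste("case", i))
        expect_equal(got$aligned_len, want$len)
        expect_equal(got$mismatches, want$mm)
      }
    }
  })
})

test_that("alignment is gapless: one inserted base destroys an exact hit", {
  ad <- adapter_spec("AGATCGGAAGAGC", 0, 6L)  # zero mismatch budget
  clean <- "ACGTACGTAGATCGGAAGAGC"
  expect_equal(align_adapter(one_read(clean), ad)$offset, 8L)
  # insert one base into the middle of the planted adapter
  mutated <- paste0(substr(clean, 1, 14), "T", substr(clean, 15, 21))
  expect_true(is.na(align_adapter(one_read(mutated), ad)$offset))
})

test_that("fixed and quality end-trimming behave as documented", {
  r <- one_read("ACGTACGT")
  expect_equal(trim_fixed_ends(r, 2L, 1L)$seq, "GTACG")
  expect_equal(trim_fixed_ends(r, 0L, 0L)$seq, "ACGTACGT")
  expect_equal(nchar(trim_fixed_ends(one_read("ACGT"), 3L, 3L)$seq), 0L)

  r <- one_read("AACCG", c(2L, 2L, 30L, 30L, 2L))
  t <- trim_low_quality_ends(r, 5L)
  expect_equal(t$seq, "CC")
  expect_equal(qual_ints(t)[[1]], c(30L, 30L))
  expect_equal(nchar(trim_low_quality_ends(one_read("AC", c(1L, 1L)), 5L)$seq),
               0L)
  expect_equal(trim_low_quality_ends(r, 0L)$seq, r$seq)
  # property: surviving terminal bases meet the threshold; length monotone
  reads <- random_read_set(200, len = 20, seed = 55)
  tr <- trim_low_quality_ends(reads, 12L)
  expect_true(all(nchar(tr$seq) <= nchar(reads$seq)))
  qs <- qual_ints(tr)
  nonempty <- lengths(qs) > 0
  expect_true(all(vapply(qs[nonempty], function(q) q[1] >= 12, logical(1))))
  expect_true(all(vapply(qs[nonempty], function(q) q[length(q)] >= 12,
                         logical(1))))
})

test_that("per-read metrics match hand arithmetic", {
  expect_equal(mean_quality(one_read("AAA", c(10L, 20L, 30L))), 20)
  expect_equal(ambiguous_fraction(one_read("ANNA")), 0.5)
  expect_equal(low_quality_fraction(one_read("ACGT", c(4L, 5L, 6L, 7L)), 5L),
               0.25)  # strict: only quality 4 counts
})

test_that("filters drop on the first failing check, either mate for pairs", {
  spec <- filter_spec()
  short <- one_read(strrep("A", 10))
  v <- apply_filters(short, spec = spec)
  expect_false(v$keep)
  expect_equal(v$reason, "short_length")
  # pair where only mate 2 is too ambiguous
  m1 <- one_read(strrep("A", 20))
  m2 <- one_read(paste0(strrep("N", 2), strrep("A", 18)))
  v <- apply_filters(m1, m2, spec)
  expect_equal(v$reason, "ambiguous_bases")
  # passing read
  v <- apply_filters(one_read(strrep("ACGT", 10)), spec = spec)
  expect_true(v$keep)
  expect_true(is.na(v$reason))
  # first-failure attribution: short AND ambiguous -> short_length wins
  both <- one_read("NNNNN")
  expect_equal(apply_filters(both, spec = spec)$reason, "short_length")
  # batch exclusion precedes everything
  b <- fq_reads("EAS1:1:FC:1:2104:3:4", strrep("N", 5),
                list(rep(2L, 5)))
  v <- apply_filters(b, spec = filter_spec(excluded_batches = "2104"),
                     batch = parse_batch_coordinate(b$id, "tile"))
  expect_equal(v$reason, "excluded_batch")
  # adapter dropping when configured
  v <- apply_filters(one_read(strrep("ACGT", 10)),
                     spec = filter_spec(drop_adapter_reads = TRUE),
                     adapter_found = TRUE)
  expect_equal(v$reason, "adapter")
})

test_that("exact threshold values never drop a read", {
  # exactly at min_length
  r <- one_read(strrep("A", 18))
  expect_true(apply_filters(r, spec = filter_spec())$keep)
  # N fraction exactly 0.05
  r <- one_read(paste0("N", strrep("A", 19)))
  expect_true(apply_filters(r, spec = filter_spec(max_n_fraction = 0.05))$keep)
  # mean quality exactly at the minimum
  r <- one_read(strrep("A", 20), rep(20L, 20))
  expect_true(apply_filters(r, spec = filter_spec(min_mean_quality = 20))$keep)
  # low-quality fraction exactly 0.5
  r <- one_read(strrep("A", 20), c(rep(2L, 10), rep(30L, 10)))
  expect_true(apply_filters(r, spec = filter_spec())$keep)
})

test_that("dedup keys depend on nucleotides only and keep first occurrences", {
  a <- one_read("ACGT", c(1L, 2L, 3L, 4L))
  b <- one_read("acgt", c(30L, 30L, 30L, 30L))
  expect_equal(dedup_key(a), dedup_key(b))
  expect_false(dedup_key(one_read("ACGA")) == dedup_key(a))
  # pairs: both mates participate
  expect_false(dedup_key(a, one_read("AAAA")) == dedup_key(a, one_read("TTTT")))
  st <- dedup_state()
  keys <- c("A", "B", "A", "A", "C")
  expect_equal(mark_duplicates(keys, st), c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # state persists across batches
  expect_equal(mark_duplicates(c("C", "D"), st), c(TRUE, FALSE))
})

test_that("DNA/RNA transforms are mutually inverse and quality-preserving", {
  r <- one_read("ACTGt", c(1L, 2L, 3L, 4L, 5L))
  rna <- transform_sequence(r, "dna_to_rna")
  expect_equal(rna$seq, "ACUGu")
  expect_identical(rna$qual, r$qual)
  expect_equal(transform_sequence(rna, "rna_to_dna")$seq, r$seq)
  expect_equal(transform_sequence(one_read("ACGN"), "dna_to_rna")$seq, "ACGN")
})

test_that("filter outcomes are order-independent with dedup off", {
  reads <- random_read_set(300, len = 25, seed = 77)
  spec <- filter_spec(min_length = 20, max_n_fraction = 0.08)
  v1 <- apply_filters(reads, spec = spec)
  perm <- withr::with_seed(1, sample(300))
  v2 <- apply_filters(reads[perm], spec = spec)
  expect_equal(v2$keep, v1$keep[perm])
  expect_equal(table(v2$reason), table(v1$reason))
})
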