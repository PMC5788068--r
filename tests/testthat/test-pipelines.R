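test_that("general pipeline is the identity on clean data with filters off", {
  fx <- generate_fixture(fixture_spec(300, read_len = 50, seed = 40))
  d <- withr::local_tempdir()
  p <- write_fixture(fx, d, "id")
  res <- run_general(p[1], out_dir = file.path(d, "out"),
                     filters = filter_spec(min_length = 0,
                                           max_n_fraction = 1,
                                           max_low_qual_fraction = 1))
  expect_equal(res$clean$n_records, 300)
  expect_equal(sum(res$clean$filter_tally), 0)
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  expect_equal(out$seq, fx$r1$seq)
  expect_equal(out$qual, fx$r1$qual)
})

test_that("general pipeline trims planted adapters at their true offsets", {
  ad <- "AGATCGGAAGAGCACACGTCT"
  fx <- generate_fixture(fixture_spec(1000, read_len = 90,
                                      adapter = adapter_spec(ad),
                                      adapter_rate = 0.1, seed = 41))
  d <- withr::local_tempdir()
  p <- write_fixture(fx, d, "ad")
  res <- run_general(p[1], out_dir = file.path(d, "out"), adapter = ad)
  expect_equal(res$clean$n_records, 1000)
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  planted <- !is.na(fx$truth$adapter_offset)
  expect_equal(nchar(out$seq)[planted], fx$truth$adapter_offset[planted])
})

test_that("deduplication removes exactly the planted duplicates", {
  fx <- generate_fixture(fixture_spec(600, read_len = 60, dup_rate = 0.12,
                                      seed = 42))
  d <- withr::local_tempdir()
  p <- write_fixture(fx, d, "dup")
  res <- run_general(p[1], out_dir = file.path(d, "out"),
                     filters = filter_spec(dedup = TRUE))
  n_dup <- sum(!is.na(fx$truth$duplicate_of))
  expect_equal(unname(res$clean$filter_tally["duplicate"]), n_dup)
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  kept <- is.na(fx$truth$duplicate_of)
  expect_equal(out$id, fx$r1$id[kept])
})

test_that("DGE tag extraction follows the anchor and length rules", {
  tag <- strrep("ACGTA", 4)  # 20 bases available after the anchor
  r <- fq_reads("t1", paste0("TT", "CATG", substr(tag, 1, 17), "GGG"),
                list(rep(30L, 26)))
  got <- find_dge_tag(r, "CATG", 17L)
  expect_true(got$found)
  expect_equal(got$reads$seq, substr(tag, 1, 17))
  expect_equal(nchar(got$reads$seq), 17L)
  # anchor absent
  expect_false(find_dge_tag(one_read(strrep("A", 30)), "CATG", 17L)$found)
  # fewer than tag_len bases after the anchor
  short <- one_read(paste0("CATG", strrep("A", 10)))
  expect_false(find_dge_tag(short, "CATG", 17L)$found)
  # leftmost anchor wins; keep_anchor prepends it
  two <- one_read(paste0("CATG", strrep("G", 17), "CATG", strrep("T", 17)))
  expect_equal(find_dge_tag(two, "CATG", 17L)$reads$seq, strrep("G", 17))
  expect_equal(find_dge_tag(two, "CATG", 17L, keep_anchor = TRUE)$reads$seq,
               paste0("CATG", strrep("G", 17)))
})

test_that("DGE pipeline outputs only N-free tags of the configured length", {
  fx <- generate_fixture(fixture_spec(500, read_len = 50,
                                      module_structure = "dge", seed = 43))
  d <- withr::local_tempdir()
  p <- write_fixture(fx, d, "dge")
  res <- run_dge(p[1], out_dir = file.path(d, "out"))
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  expect_equal(length(out), 500L)
  expect_true(all(nchar(out$seq) == 17L))
  expect_false(any(grepl("N", out$seq)))
  expect_equal(out$seq, fx$truth$tag)
  # a read whose tag holds an N is dropped as ambiguous
  withN <- fq_reads(c("ok", "bad"),
                    c(paste0("CATG", strrep("A", 17)),
                      paste0("CATG", strrep("A", 8), "N", strrep("A", 8))),
                    list(rep(30L, 21), rep(30L, 21)))
  tf <- file.path(d, "n.fq")
  write_fastq(withN, tf)
  res <- run_dge(tf, out_dir = file.path(d, "out2"), in_encoding = "phred33")
  expect_equal(unname(res$clean$filter_tally["ambiguous_bases"]), 1)
  expect_equal(res$clean$n_records, 1)
  # anchor-less reads are dropped and tallied
  noanchor <- one_read(strrep("T", 30), id = "na1")
  tf2 <- file.path(d, "na.fq")
  write_fastq(noanchor, tf2)
  res <- run_dge(tf2, out_dir = file.path(d, "out3"), in_encoding = "phred33")
  expect_equal(unname(res$clean$filter_tally["dge_tag_missing"]), 1)
})

test_that("poly-A calls use the at-least-threshold rule", {
  expect_true(is_polya(one_read(strrep("A", 10)), 0.7))
  expect_false(is_polya(one_read(paste0(strrep("A", 6), "CGTC")), 0.7))
  expect_true(is_polya(one_read(paste0(strrep("A", 7), "CGT")), 0.7))
  expect_false(is_polya(one_read(""), 0.7))
})

test_that("sRNA pipeline trims adapters, drops poly-A and enforces the window", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  fx <- generate_fixture(fixture_spec(800, read_len = 49,
                                      module_structure = "srna",
                                      adapter = adapter_spec(ad),
                                      contaminant_rate = 0.1, seed = 44))
  d <- withr::local_tempdir()
  p <- write_fixture(fx, d, "sr")
  res <- run_srna(p[1], out_dir = file.path(d, "out"), adapter = ad)
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  # all output lengths equal the planted insert lengths, inside 18..30
  expect_true(all(nchar(out$seq) >= 18 & nchar(out$seq) <= 30))
  m <- match(out$id, fx$r1$id)
  expect_equal(nchar(out$seq), fx$truth$insert_len[m])
  # contaminants tallied under polya, absent from output
  expect_equal(unname(res$clean$filter_tally["polya"]), sum(fx$truth$polya))
  expect_false(any(out$id %in% fx$r1$id[fx$truth$polya]))
  expect_false(any(is_polya(out, 0.7)))
  # an insert longer than the window is dropped by the length check
  long <- one_read(paste0(strrep("ACG", 12), substr(ad, 1, 13)), id = "lng")
  tf <- file.path(d, "lng.fq")
  write_fastq(long, tf)
  res2 <- run_srna(tf, out_dir = file.path(d, "out2"), adapter = ad,
                   in_encoding = "phred33")
  expect_equal(unname(res2$clean$filter_tally["short_length"]), 1)
})

test_that("meta pipeline trims ends, filters length/N only, honors overrides", {
  fx <- generate_fixture(fixture_spec(400, read_len = 60, n_rate = 0.02,
                                      dup_rate = 0.1, seed = 45))
  # degrade 3' tails
  tails <- lapply(qual_ints(fx$r1), function(q) {
    q[(length(q) - 4):length(q)] <- 3L
    q
  })
  r1 <- fq_reads(fx$r1$id, fx$r1$seq, tails)
  d <- withr::local_tempdir()
  tf <- file.path(d, "meta.fq")
  write_fastq(r1, tf)
  res <- run_meta(tf, out_dir = file.path(d, "out"), qual_trim = 20L)
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  lastq <- vapply(qual_ints(out), function(q) q[length(q)], integer(1))
  expect_true(all(lastq >= 20L))
  # mean-quality / low-qual filters and dedup are off by default
  expect_equal(unname(res$clean$filter_tally["duplicate"]), 0)
  expect_equal(unname(res$clean$filter_tally["low_mean_quality"]), 0)
  # forcing dedup on is honored
  res2 <- run_meta(tf, out_dir = file.path(d, "out2"), qual_trim = 20L,
                   filters = filter_spec(min_mean_quality = 0,
                                         max_low_qual_fraction = 1,
                                         dedup = TRUE))
  expect_equal(unname(res2$clean$filter_tally["duplicate"]),
               sum(!is.na(fx$truth$duplicate_of)))
  # a read with 20% N is dropped under the strict rule
  n20 <- one_read(paste0(strrep("N", 12), strrep("A", 48)))
  tf2 <- file.path(d, "n20.fq")
  write_fastq(n20, tf2)
  res3 <- run_meta(tf2, out_dir = file.path(d, "out3"), in_encoding = "phred33")
  expect_equal(unname(res3$clean$filter_tally["ambiguous_bases"]), 1)
})

test_that("conservation holds for every module on mixed fixtures", {
  d <- withr::local_tempdir()
  ad <- "AGATCGGAAGAGC"
  fx <- generate_fixture(fixture_spec(500, read_len = 70,
                                      adapter = adapter_spec(ad),
                                      adapter_rate = 0.15, dup_rate = 0.1,
                                      n_rate = 0.01, seed = 46))
  p <- write_fixture(fx, d, "gen")
  runs <- list(
    run_general(p[1], out_dir = file.path(d, "o1"), adapter = ad,
                filters = filter_spec(dedup = TRUE)),
    run_meta(p[1], out_dir = file.path(d, "o2"), adapter = ad, qual_trim = 5L)
  )
  fxd <- generate_fixture(fixture_spec(300, read_len = 50,
                                       module_structure = "dge", seed = 47))
  pd <- write_fixture(fxd, d, "dge")
  runs$dge <- run_dge(pd[1], out_dir = file.path(d, "o3"))
  fxs <- generate_fixture(fixture_spec(300, read_len = 49,
                                       module_structure = "srna",
                                       adapter = adapter_spec(ad),
                                       seed = 48))
  ps <- write_fixture(fxs, d, "srna")
  runs$srna <- run_srna(ps[1], out_dir = file.path(d, "o4"), adapter = ad)
  for (res in runs) {
    expect_equal(res$raw$n_records,
                 res$clean$n_records + sum(res$clean$filter_tally))
  }
})

test_that("batch exclusion drops reads from listed tiles", {
  ids <- sprintf("M:1:FC:1:%d:%d:%d", rep(c(1101, 2104), each = 10), 1:20, 1:20)
  reads <- fq_reads(ids, rep(strrep("ACGT", 10), 20),
                    lapply(1:20, function(i) rep(30L, 40)))
  d <- withr::local_tempdir()
  tf <- file.path(d, "tiles.fq")
  write_fastq(reads, tf)
  res <- run_general(tf, out_dir = file.path(d, "out"),
                     in_encoding = "phred33",
                     filters = filter_spec(excluded_batches = "2104",
                                           batch_kind = "tile"))
  expect_equal(unname(res$clean$filter_tally["excluded_batch"]), 10)
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  expect_false(any(grepl(":2104:", out$id)))
})

test_that("RNA transform is applied to clean output only", {
  reads <- fq_reads("r", strrep("ACGT", 10), list(rep(30L, 40)))
  d <- withr::local_tempdir()
  tf <- file.path(d, "t.fq")
  write_fastq(reads, tf)
  run_general(tf, out_dir = file.path(d, "out"), transform = "dna_to_rna",
              in_encoding = "phred33")
  out <- read_fastq(file.path(d, "out", "clean.fq"), "phred33")
  expect_equal(out$seq, strrep("ACGU", 10))
})
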