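test_that("counts accumulate, saturate at 255, and reject invalid k-mers", {
  s <- tiny_sketch(3)
  expect_identical(cm_add(s, "AAA"), 1L)
  expect_identical(cm_count(s, "AAA"), 1L)
  expect_identical(cm_count(s, "CCC"), 0L)
  for (i in 1:264) cm_add(s, "GAT")
  expect_identical(cm_count(s, "GAT"), 255L)
  expect_error(cm_add(s, "ANA"), "ambiguous")
  expect_error(cm_add(s, "AAAA"), "length")
  expect_error(cm_count(s, "AXA"), "invalid alphabet")
})

test_that("a k-mer and its reverse complement share one counter", {
  s <- tiny_sketch(4)
  cm_add(s, "AACG")
  expect_identical(cm_count(s, "CGTT"), 1L)
  # stranded sketches keep them apart
  s2 <- countmin_sketch(kmer_spec(4, canonical = FALSE), table_size = 1e4)
  cm_add(s2, "AACG")
  expect_identical(cm_count(s2, "CGTT"), 0L)
  expect_identical(cm_count(s2, "AACG"), 1L)
})

test_that("consume_sequence adds every valid window and skips ambiguous ones", {
  s <- tiny_sketch(3)
  n <- consume_sequence(s, "AAAAA")
  expect_equal(as.numeric(n), 3)
  expect_identical(cm_count(s, "AAA"), 3L)
  s2 <- tiny_sketch(2)
  n2 <- consume_sequence(s2, "AANAA")
  expect_equal(as.numeric(n2), 2)
  expect_equal(attr(n2, "skipped_windows"), 2)
  # stream/batch equivalence: one call over all reads vs read-at-a-time
  set.seed(21)
  reads <- simulate_reads(simulate_genome(400, 1), 60, 4, 0.01, seed = 2)
  sa <- tiny_sketch(9, table_size = 1e5)
  sb <- tiny_sketch(9, table_size = 1e5)
  consume_sequence(sa, reads$sequence)
  for (r in reads$sequence) consume_sequence(sb, r)
  probes <- unique(unlist(lapply(reads$sequence[1:20],
                                 function(x) as.character(oracle_kmers(x, 9)))))
  expect_identical(cm_count(sa, probes), cm_count(sb, probes))
})

test_that("estimates never undercount and match the exact counter without collisions", {
  set.seed(5)
  genome <- simulate_genome(2000, 31)
  reads <- simulate_reads(genome, 80, 8, 0.005, seed = 32)
  s <- countmin_sketch(kmer_spec(12), table_size = 1e5)
  consume_sequence(s, reads$sequence)
  tab <- oracle_counts(reads$sequence, 12)
  km <- names(tab)
  est <- cm_count(s, km)
  exact <- as.integer(tab)
  expect_true(all(est >= pmin(exact, 255L)))
  # with tables of ~1e5 cells this stream is essentially collision-free
  expect_gte(mean(est == exact), 0.99)
  # never-seen k-mers mostly report zero
  set.seed(6)
  fresh <- setdiff(random_kmers(500, 12), km)
  expect_gte(mean(cm_count(s, fresh) == 0L), 0.98)
})

test_that("one table's cell sum equals the number of k-mers consumed before saturation", {
  set.seed(8)
  s <- tiny_sketch(6, table_size = 5e4)
  reads <- simulate_reads(simulate_genome(500, 41), 50, 3, 0, seed = 42)
  n <- as.numeric(consume_sequence(s, reads$sequence))
  for (i in 1:4) {
    cells <- as.integer(kmersieve:::.cms_table_bytes(s$ptr, i))
    expect_lt(max(cells), 255L)  # pre-saturation regime
    expect_equal(sum(cells), n)
  }
})

test_that("median_count implements the upper median with query-only semantics", {
  s <- tiny_sketch(3)
  consume_sequence(s, "AAAAA")
  m <- median_count(s, "AAAAA")
  expect_equal(m$median, 3)
  expect_equal(m$mean, 3)
  expect_equal(m$sd, 0)
  # querying twice gives the same answer: nothing was added
  expect_equal(median_count(s, "AAAAA")$median, 3)
  # fresh sketch: all zeros
  m0 <- median_count(tiny_sketch(3), "ACGTACG")
  expect_equal(c(m0$median, m0$mean, m0$sd), c(0, 0, 0))
  expect_error(median_count(s, "AA"), "no valid k-mers")
  # upper-median convention: spectrum c(1, 1, 9) has median 1 (sorted index
  # floor(3/2) = 1, 0-based), and an even-length spectrum takes the upper
  # of the two central elements
  s2 <- tiny_sketch(3)
  consume_sequence(s2, c("ACGGA", "CGGA"))  # counts: ACG 1, CGG 2, GGA 2
  m2 <- median_count(s2, "ACGGA")           # spectrum 1, 2, 2 -> median 2
  expect_equal(m2$median, 2)
  s3 <- tiny_sketch(3)
  consume_sequence(s3, "ACGG")              # ACG 1, CGG 1
  expect_equal(median_count(s3, "ACGG")$median, 1)
})

test_that("abundance distribution bins every distinct k-mer exactly once", {
  s <- tiny_sketch(3)
  consume_sequence(s, "AAAA")
  d <- abundance_distribution(s, "AAAA")
  expect_equal(d$n_kmers[d$abundance == 2], 1)
  expect_equal(sum(d$n_kmers), 1)  # one distinct canonical k-mer
  # all-unique non-overlapping k-mers -> all mass in bin 1
  km <- c("ACGGT", "TCCAG", "GATTC")
  s2 <- tiny_sketch(5)
  consume_sequence(s2, km)
  d2 <- abundance_distribution(s2, km)
  expect_equal(d2$n_kmers[d2$abundance == 1], 3)
  # bins sum to the number of distinct canonical k-mers on simulated reads
  set.seed(9)
  reads <- simulate_reads(simulate_genome(800, 51), 60, 6, 0.01, seed = 52)
  s3 <- countmin_sketch(kmer_spec(10), table_size = 1e5)
  consume_sequence(s3, reads$sequence)
  d3 <- abundance_distribution(s3, reads)
  expect_equal(sum(d3$n_kmers), length(oracle_counts(reads$sequence, 10)))
})

test_that("fp_rate is the product of table occupancies and predicts fresh-k-mer hits", {
  s <- tiny_sketch(8, table_size = 997, n_tables = 2)
  expect_equal(fp_rate(s), 0)
  set.seed(12)
  stream <- vapply(1:60, function(i)
    paste(sample(c("A","C","G","T"), 40, TRUE), collapse = ""), "")
  consume_sequence(s, stream)
  occ <- kmersieve:::.cms_info(s$ptr)$occupancy
  expect_equal(fp_rate(s), prod(occ))
  # empirical nonzero rate of never-inserted k-mers tracks the occupancy
  # product within Monte-Carlo noise
  inserted <- names(oracle_counts(stream, 8))
  probes <- setdiff(random_kmers(12000, 8), inserted)
  probes <- setdiff(probes, oracle_revcomp_vec(inserted, 8))
  hit <- mean(cm_count(s, probes) > 0)
  expect_lt(abs(hit - fp_rate(s)), 0.02)
})

test_that("sketch serialization round-trips bit-exactly and validates its header", {
  set.seed(14)
  s <- tiny_sketch(7, table_size = 5003)
  consume_sequence(s, simulate_reads(simulate_genome(300, 61), 50, 4, 0.02,
                                     seed = 62)$sequence)
  path <- withr::local_tempfile(fileext = ".mkm")
  save_sketch(s, path)
  s2 <- load_sketch(path)
  probes <- random_kmers(600, 7)
  expect_identical(cm_count(s2, probes), cm_count(s, probes))
  expect_identical(s2$family$table_sizes, s$family$table_sizes)

  # truncation is a loud, named failure
  bytes <- readBin(path, "raw", file.size(path))
  half <- withr::local_tempfile()
  writeBin(bytes[1:(length(bytes) %/% 2)], half)
  expect_error(load_sketch(half), "corrupt file.*table_payload",
               ignore.case = TRUE)
  short <- withr::local_tempfile()
  writeBin(bytes[1:6], short)
  expect_error(load_sketch(short), "field 'k'|field 'canonical'")
  # wrong magic
  bad <- bytes; bad[1] <- as.raw(77L + 1L)
  badf <- withr::local_tempfile()
  writeBin(bad, badf)
  expect_error(load_sketch(badf), "bad magic")
  # a graph file is not a sketch file
  g <- tiny_graph(7)
  gp <- withr::local_tempfile()
  save_graph(g, gp)
  expect_error(load_sketch(gp), "bad magic")

  # k recorded in the header travels with the sketch: a mismatched spec is
  # refused by consumers
  p5 <- diginorm_params(3, spec = kmer_spec(5), table_size = 1e4)
  expect_error(normalize_by_median(sequence_records("r", "ACGTACGT"), p5,
                                   sketch = s2),
               "k = 7.*k = 5")
})
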