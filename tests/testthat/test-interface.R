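# Display methods and the less-traveled error/validation branches of the
# user-facing surface.

test_that("print methods summarise the core objects informatively", {
  s <- tiny_sketch(5, table_size = 1e4)
  consume_sequence(s, "ACGTACGTAC")
  expect_output(print(s), "countmin_sketch.*k = 5.*canonical")
  expect_output(print(s), "k-mers consumed: 6")
  g <- tiny_graph(5, table_size = 1e4)
  consume_graph(g, "ACGTACGTAC")
  expect_output(print(g), "node_graph.*k = 5")
  expect_output(print(g), "nodes added")
  expect_output(print(kmer_spec(4, canonical = FALSE)), "stranded")
  recs <- sequence_records("r", "ACGT", "IIII")
  expect_output(print(recs), "1 records.*with qualities")
  expect_output(print(sequence_records("r", "ACGT")), "FASTA, no qualities")
  res <- normalize_by_median(recs, diginorm_params(2, kmer_spec(3),
                                                   table_size = 1e4))
  expect_output(print(res), "kept 1")
  fr <- filter_abund(recs, countmin_sketch(kmer_spec(3), table_size = 1e4),
                     trim_params(1))
  expect_output(print(fr), "seen 1")
})

test_that("sketch and graph constructors validate their arguments", {
  expect_error(countmin_sketch(list(k = 5)), "kmer_spec")
  expect_error(node_graph("x"), "kmer_spec")
  expect_error(countmin_sketch(kmer_spec(5), family = list(a = 1)),
               "hash_family")
  expect_error(cm_add(list(), "AAA"), "countmin_sketch")
  expect_error(add_node(list(), "AAA"), "node_graph")
  expect_error(fp_rate(42), "countmin_sketch.*node_graph")
  expect_error(normalize_by_median(sequence_records("a", "AC"), list()),
               "diginorm_params")
  expect_error(trim_low_abundance(sequence_records("a", "ACGT"),
                                  tiny_sketch(3), list()), "trim_params")
  expect_error(trim_params(0), "positive")
  expect_error(hash_indices("AC", hash_family(2, 100), "spec"), "kmer_spec")
  # graph fp rate follows the same occupancy-product law as the sketch
  g <- tiny_graph(6, table_size = 499, n_tables = 2)
  expect_equal(fp_rate(g), 0)
  consume_graph(g, strrep("ACGGTCAT", 20))
  expect_equal(fp_rate(g), prod(kmersieve:::.ng_info(g$ptr)$occupancy))
  expect_gt(fp_rate(g), 0)
})

test_that("corrupt container headers are rejected field by field", {
  s <- tiny_sketch(4, table_size = 101, n_tables = 2)
  cm_add(s, "ACGT")
  path <- withr::local_tempfile()
  save_sketch(s, path)
  bytes <- readBin(path, "raw", file.size(path))
  patch <- function(at, value) {
    b <- bytes
    b[at] <- as.raw(value)
    f <- withr::local_tempfile(.local_envir = parent.frame())
    writeBin(b, f)
    f
  }
  # byte 5 = version, 6 = k, 7 = canonical flag, 8 = n_tables
  expect_error(load_sketch(patch(5, 9)), "unsupported version")
  expect_error(load_sketch(patch(7, 7)), "field 'canonical'")
  expect_error(load_sketch(patch(8, 0)), "field 'n_tables'")
  # trailing garbage is noticed
  f <- withr::local_tempfile()
  writeBin(c(bytes, as.raw(1)), f)
  expect_error(load_sketch(f), "trailing bytes")
  # a truncated header dies on the table size, not silently
  f2 <- withr::local_tempfile()
  writeBin(bytes[1:18], f2)
  expect_error(load_sketch(f2), "table_size|table_payload")
})

test_that("seed scoping restores or clears the caller's RNG state", {
  # with no pre-existing RNG state the generator leaves none behind
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(simulate_genome(50, 1))
  expect_false(exists(".Random.seed", globalenv(), inherits = FALSE))
  # with state, it is restored exactly
  set.seed(42)
  want <- .Random.seed
  invisible(simulate_reads(simulate_genome(100, 2), 20, 2, 0.1, seed = 3))
  expect_identical(.Random.seed, want)
})

test_that("normalize-by-median persists and resumes its sketch from the shell", {
  genome <- simulate_genome(600, 241)
  reads <- simulate_reads(genome, 60, 10, 0, seed = 242)
  half1 <- withr::local_tempfile(fileext = ".fq")
  half2 <- withr::local_tempfile(fileext = ".fq")
  n <- nrow(reads)
  write_records(reads[1:(n %/% 2), ], half1)
  write_records(reads[(n %/% 2 + 1):n, ], half2)
  whole <- withr::local_tempfile(fileext = ".fq")
  write_records(reads, whole)

  tab <- withr::local_tempfile(fileext = ".mkm")
  out1 <- withr::local_tempfile(fileext = ".fq")
  out2 <- withr::local_tempfile(fileext = ".fq")
  outw <- withr::local_tempfile(fileext = ".fq")
  args <- c("-C", "4", "-k", "12", "-x", "100003")
  r1 <- run_cli("normalize-by-median", args, "--savetable", tab,
                "-o", out1, half1)
  expect_identical(r1$status, 0L)
  r2 <- run_cli("normalize-by-median", args, "--loadtable", tab,
                "-o", out2, half2)
  expect_identical(r2$status, 0L)
  rw <- run_cli("normalize-by-median", args, "-o", outw, whole)
  expect_identical(rw$status, 0L)
  expect_identical(c(read_records(out1)$id, read_records(out2)$id),
                   read_records(outw)$id)
  # loading a table with a different k is refused as a data error
  r3 <- run_cli("normalize-by-median", "-C", "4", "-k", "10", "--loadtable",
                tab, "-o", tempfile(), half2)
  expect_identical(r3$status, 2L)
  expect_match(paste(r3$stderr, collapse = "\n"), "k = 12")
})

test_that("remaining command usage errors are caught before any work happens", {
  expect_identical(run_cli("abund-dist", "one-arg-only")$status, 1L)
  expect_identical(run_cli("normalize-by-median", "-o", "x")$status, 1L)
  expect_identical(run_cli("normalize-by-median", "a", "b")$status, 1L)
  expect_identical(run_cli("filter-abund", "-o", "x", "sketch")$status, 1L)
  expect_identical(run_cli("filter-abund", "sketch", "reads")$status, 1L)
  expect_identical(run_cli("quality-filter", "reads")$status, 1L)
  expect_identical(run_cli("quality-filter", "-o", "x", "a", "b")$status, 1L)
  expect_identical(run_cli("partition", "-o", "x")$status, 1L)
  expect_identical(run_cli("partition", "reads")$status, 1L)
  expect_identical(run_cli("count", "-o", "x")$status, 1L)
  expect_identical(run_cli("simulate", "--length", "100")$status, 1L)
  expect_identical(run_cli("simulate", "--length", "100", "--coverage", "2",
                           "--read-length", "50")$status, 1L)
  expect_identical(run_cli("count", "-k", "notanumber", "-o", "x", "y")$status,
                   1L)
  expect_identical(run_cli("simulate", "--coverage", "NaN")$status, 1L)
  # a FASTA input with a quality threshold is a data error at run time
  fa <- withr::local_tempfile(fileext = ".fa")
  write_records(sequence_records("a", "ACGT"), fa)
  r <- run_cli("quality-filter", "--min-mean-q", "20", fa, "-o", tempfile())
  expect_identical(r$status, 2L)
})

test_that("a failing pipeline stage aborts the chain but keeps earlier outputs", {
  genome <- simulate_genome(500, 251)
  reads <- simulate_reads(genome, 60, 5, 0, seed = 252)
  fq <- withr::local_tempfile(fileext = ".fq")
  write_records(reads, fq)
  wd <- withr::local_tempdir()
  # an impossible normalization cutoff (>= counter cap) fails its stage
  expect_error(suppressMessages(
    run_acceptance_pipeline(fq, wd, cutoff = 300, table_size = 1e5)),
    "normalize-by-median.*failed")
  expect_true(file.exists(file.path(wd, "s1_quality.fq")))
  expect_true(file.exists(file.path(wd, "counts.mkm")))
  expect_true(file.exists(file.path(wd, "s2_trimmed.fq")))
  expect_false(file.exists(file.path(wd, "s3_normalized.fq")))
  expect_error(run_acceptance_pipeline("/nonexistent.fq", wd), "cannot read")
  # FASTA inputs flow through with .fa stage names
  fa <- withr::local_tempfile(fileext = ".fa")
  write_records(sequence_records(reads$id, reads$sequence), fa)
  wd2 <- withr::local_tempdir()
  res <- run_acceptance_pipeline(fa, wd2, k = 12, table_size = 1e5)
  expect_true(file.exists(file.path(wd2, "s3_normalized.fa")))
  expect_output(print(res), "pipeline_result")
})
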