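#' Create a CountMin sketch for approximate k-mer counting
#'
#' A CountMin sketch estimates k-mer abundances in fixed memory: `N` counter
#' tables of distinct prime sizes, each addressed by the same mixed hash
#' reduced modulo the table's prime. A k-mer's reported count is the minimum
#' over its `N` cells, so estimates can only err upward (hash collisions
#' inflate, never deflate, a count). Counters are 8-bit and saturate at 255,
#' which is ample for coverage-threshold decisions.
#'
#' Sketches have reference semantics: `cm_add()` and `consume_sequence()`
#' update the sketch in place (the underlying tables live in external
#' memory), which is what makes single-pass streaming algorithms possible.
#'
#' @param spec A [kmer_spec()].
#' @param family Optional [hash_family()]; defaults to
#'   `hash_family(n_tables, table_size)`.
#' @param n_tables,table_size Used when `family` is NULL.
#' @return An object of class `countmin_sketch`.
#' @examples
#' s <- countmin_sketch(kmer_spec(5), n_tables = 4, table_size = 1e4)
#' consume_sequence(s, "ACGTACGTACGT")
#' cm_count(s, "ACGTA")
#' @export
countmin_sketch <- function(spec, family = NULL, n_tables = 4, table_size = 1e6) {
  spec <- as_kmer_spec(spec)
  family <- resolve_family(family, n_tables, table_size)
  ptr <- .cms_new(spec$k, spec$canonical, family$table_sizes)
  structure(list(ptr = ptr, spec = spec, family = family),
            class = "countmin_sketch")
}

as_cms <- function(sketch) {
  if (!inherits(sketch, "countmin_sketch")) {
    stop("expected a 'countmin_sketch' object; see countmin_sketch()", call. = FALSE)
  }
  sketch
}

#' @export
print.countmin_sketch <- function(x, ...) {
  info <- .cms_info(x$ptr)
  cat(sprintf("<countmin_sketch> k = %d (%s), %d tables\n",
              info$k, if (info$canonical) "canonical" else "stranded",
              length(info$table_sizes)))
  cat(sprintf("  table sizes: %s\n",
              paste(format(info$table_sizes, scientific = FALSE), collapse = ", ")))
  cat(sprintf("  k-mers consumed: %.0f; skipped windows: %.0f; fp rate: %.3g\n",
              info$n_consumed, info$n_skipped_windows, fp_rate(x)))
  invisible(x)
}

#' Add one k-mer to a sketch
#'
#' Increments the k-mer's cell in every table (saturating at 255) and
#' returns the new estimated count (minimum over tables).
#'
#' @param sketch A [countmin_sketch()].
#' @param kmer A single k-mer of length `k`, no ambiguous bases.
#' @return The estimated count after the increment.
#' @export
cm_add <- function(sketch, kmer) {
  sketch <- as_cms(sketch)
  .cms_add(sketch$ptr, kmer)
}

#' Query estimated k-mer counts
#'
#' Returns the minimum over tables of the k-mer's cells; never modifies the
#' sketch. Estimates are exact when the k-mer collided with nothing in at
#' least one table, and otherwise overcounts.
#'
#' @param sketch A [countmin_sketch()].
#' @param kmers Character vector of k-mers.
#' @return Integer vector of estimated counts.
#' @export
cm_count <- function(sketch, kmers) {
  sketch <- as_cms(sketch)
  .cms_get(sketch$ptr, kmers)
}

#' Count all k-mers of sequences into a sketch
#'
#' Every valid window of every sequence is added in order; windows covering
#' a non-ACGT character are skipped (and tallied), the sequences themselves
#' are never altered.
#'
#' @param sketch A [countmin_sketch()].
#' @param seqs Character vector of DNA sequences (reads).
#' @return The number of k-mers added, with the cumulative number of skipped
#'   windows as attribute `skipped_windows`.
#' @export
consume_sequence <- function(sketch, seqs) {
  sketch <- as_cms(sketch)
  stopifnot(is.character(seqs))
  res <- .cms_consume(sketch$ptr, seqs)
  structure(res$added, skipped_windows = res$skipped)
}

#' Median/mean/sd of a sequence's k-mer count spectrum
#'
#' Queries (without adding) the sketch count of every valid k-mer in `seq`
#' and summarises the spectrum. The median is the upper median: element
#' `floor(n/2)` (0-based) of the sorted count list. `sd` is the population
#' standard deviation (0 for a single k-mer). This summary is the decision
#' statistic of digital normalization: the median k-mer count of a read is a
#' robust estimate of the coverage of its locus.
#'
#' @param sketch A [countmin_sketch()].
#' @param seq A single DNA sequence with at least one valid k-mer.
#' @return A list with elements `median`, `mean`, `sd` and `n_kmers`.
#' @export
median_count <- function(sketch, seq) {
  sketch <- as_cms(sketch)
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- .cms_median(sketch$ptr, seq)
  list(median = v[[1]], mean = v[[2]], sd = v[[3]], n_kmers = as.integer(v[[4]]))
}

#' Abundance histogram of the distinct k-mers in a read set
#'
#' Each distinct canonical k-mer occurring in `reads` contributes exactly
#' once, to the bin of its sketch count (bins 0..255; distinctness is
#' tracked with an exact set, so this is intended for desk-scale read sets).
#' The sketch should already have been loaded with the same reads (or a
#' superset) via [consume_sequence()].
#'
#' @param sketch A [countmin_sketch()].
#' @param reads Character vector of sequences, or a records data.frame from
#'   [read_records()].
#' @return A data.frame with columns `abundance` (0..255) and `n_kmers`.
#' @export
abundance_distribution <- function(sketch, reads) {
  sketch <- as_cms(sketch)
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(is.character(seqs))
  hist <- .cms_abund_dist(sketch$ptr, seqs)
  data.frame(abundance = 0:255, n_kmers = as.numeric(hist))
}

#' Estimated false-positive rate of a sketch or graph
#'
#' The probability that a never-inserted k-mer reports a nonzero count
#' (sketch) or presence (graph): the product over tables of the fraction of
#' occupied cells, since tables are addressed independently modulo distinct
#' primes.
#'
#' @param x A [countmin_sketch()] or [node_graph()].
#' @return A single numeric in \[0, 1\].
#' @export
fp_rate <- function(x) {
  if (inherits(x, "countmin_sketch")) {
    prod(.cms_info(x$ptr)$occupancy)
  } else if (inherits(x, "node_graph")) {
    prod(.ng_info(x$ptr)$occupancy)
  } else {
    stop("expected a 'countmin_sketch' or 'node_graph' object", call. = FALSE)
  }
}

# ---- serialization --------------------------------------------------------
# Shared header: magic (4 bytes), version u8, k u8, canonical u8, n_tables
# u8, then per table its size as u64 little-endian followed by the raw
# payload (counter bytes for sketches, packed bits for graphs).

write_u64 <- function(con, x) {
  lo <- x %% 4294967296
  hi <- x %/% 4294967296
  as_i32 <- function(v) as.integer(if (v >= 2147483648) v - 4294967296 else v)
  writeBin(c(as_i32(lo), as_i32(hi)), con, size = 4L, endian = "little")
}

read_u64 <- function(con, field) {
  w <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(w) < 2L) {
    stop(sprintf("corrupt file: truncated while reading field '%s'", field),
         call. = FALSE)
  }
  u <- ifelse(w < 0, w + 4294967296, w)
  u[[1]] + u[[2]] * 4294967296
}

read_u8 <- function(con, field) {
  b <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
  if (length(b) < 1L) {
    stop(sprintf("corrupt file: truncated while reading field '%s'", field),
         call. = FALSE)
  }
  b
}

save_tables <- function(path, magic, spec, sizes, payloads, n_consumed) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(magic), con)
  writeBin(as.raw(c(1L, spec$k, as.integer(spec$canonical), length(sizes))), con)
  write_u64(con, n_consumed)
  for (i in seq_along(sizes)) {
    write_u64(con, sizes[[i]])
    writeBin(payloads[[i]], con)
  }
  invisible(path)
}

load_tables <- function(path, magic, payload_len) {
  con <- file(path, "rb")
  on.exit(close(con))
  m <- readBin(con, "raw", n = 4L)
  if (length(m) < 4L || !identical(rawToChar(m), magic)) {
    stop(sprintf("corrupt file: bad magic (field 'magic'; expected \"%s\")", magic),
         call. = FALSE)
  }
  version <- read_u8(con, "version")
  if (version != 1L) {
    stop(sprintf("corrupt file: unsupported version %d (field 'version')", version),
         call. = FALSE)
  }
  k <- read_u8(con, "k")
  canonical <- read_u8(con, "canonical")
  if (!canonical %in% c(0L, 1L)) {
    stop("corrupt file: invalid value (field 'canonical')", call. = FALSE)
  }
  n_tables <- read_u8(con, "n_tables")
  if (n_tables < 1L) {
    stop("corrupt file: invalid value (field 'n_tables')", call. = FALSE)
  }
  n_consumed <- read_u64(con, "n_consumed")
  sizes <- numeric(n_tables)
  payloads <- vector("list", n_tables)
  for (i in seq_len(n_tables)) {
    sizes[[i]] <- read_u64(con, sprintf("table_size[%d]", i))
    if (sizes[[i]] < 3) {
      stop(sprintf("corrupt file: invalid value (field 'table_size[%d]')", i),
           call. = FALSE)
    }
    want <- payload_len(sizes[[i]])
    payloads[[i]] <- readBin(con, "raw", n = want)
    if (length(payloads[[i]]) < want) {
      stop(sprintf("corrupt file: truncated while reading field 'table_payload[%d]'", i),
           call. = FALSE)
    }
  }
  if (length(readBin(con, "raw", n = 1L)) != 0L) {
    stop("corrupt file: trailing bytes after last table (field 'eof')", call. = FALSE)
  }
  list(k = k, canonical = canonical == 1L, sizes = sizes,
       payloads = payloads, n_consumed = n_consumed)
}

#' Save / load a CountMin sketch
#'
#' The on-disk format is a small validated header (magic `"MKM1"`, format
#' version, k, canonical flag, table count) followed by each table's prime
#' size (unsigned 64-bit little-endian) and raw counter bytes. A round trip
#' reproduces identical counts for every query; corrupt or truncated files
#' raise an error naming the failing field.
#'
#' @param sketch A [countmin_sketch()].
#' @param path File path.
#' @return `save_sketch()` returns `path` invisibly; `load_sketch()` returns
#'   a `countmin_sketch`.
#' @export
save_sketch <- function(sketch, path) {
  sketch <- as_cms(sketch)
  info <- .cms_info(sketch$ptr)
  payloads <- lapply(seq_along(info$table_sizes),
                     function(i) .cms_table_bytes(sketch$ptr, i))
  save_tables(path, "MKM1", sketch$spec, info$table_sizes, payloads,
              info$n_consumed)
  invisible(path)
}

#' @rdname save_sketch
#' @export
load_sketch <- function(path) {
  dat <- load_tables(path, "MKM1", payload_len = function(size) size)
  spec <- kmer_spec(dat$k, dat$canonical)
  family <- structure(list(table_sizes = dat$sizes), class = "hash_family")
  sketch <- countmin_sketch(spec, family = family)
  for (i in seq_along(dat$payloads)) {
    .cms_set_table_bytes(sketch$ptr, i, dat$payloads[[i]], dat$n_consumed)
  }
  sketch
}

check_spec_match <- function(obj_spec, spec, what) {
  if (obj_spec$k != spec$k || obj_spec$canonical != spec$canonical) {
    stop(sprintf(
      "%s was built with k = %d (%s) and cannot be used with k = %d (%s)",
      what, obj_spec$k,
      if (obj_spec$canonical) "canonical" else "stranded",
      spec$k, if (spec$canonical) "canonical" else "stranded"),
      call. = FALSE)
  }
  invisible(TRUE)
}
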