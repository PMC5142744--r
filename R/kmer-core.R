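#' Define a k-mer specification
#'
#' A `kmer_spec` fixes the k-mer length and the canonicalization policy
#' shared by every sketch and graph structure built from it. With
#' `canonical = TRUE` (the default) each k-mer is collapsed with its reverse
#' complement onto the lexicographically smaller of the two, so forward and
#' reverse reads of the same locus count as one entity.
#'
#' `k` must lie in 1..32 so a k-mer packs into a 64-bit word at 2 bits per
#' base; typical values for short-read pre-filtering are 20-30.
#'
#' @param k Integer k-mer length in bases (1..32).
#' @param canonical Logical; collapse each k-mer with its reverse complement.
#' @return An object of class `kmer_spec`.
#' @examples
#' kmer_spec(20)
#' @export
kmer_spec <- function(k, canonical = TRUE) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 32L) {
    stop("k must be a single integer between 1 and 32 (2-bit packing in a 64-bit word)",
         call. = FALSE)
  }
  stopifnot(is.logical(canonical), length(canonical) == 1L, !is.na(canonical))
  structure(list(k = k, canonical = canonical), class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf("<kmer_spec> k = %d, %s\n", x$k,
              if (x$canonical) "canonical (strand-collapsed)" else "stranded"))
  invisible(x)
}

as_kmer_spec <- function(spec) {
  if (!inherits(spec, "kmer_spec")) {
    stop("expected a 'kmer_spec' object; see kmer_spec()", call. = FALSE)
  }
  spec
}

is_prime <- function(n) {
  if (n < 2) return(FALSE)
  if (n < 4) return(TRUE)
  if (n %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

#' Construct the hash family backing sketches and graphs
#'
#' The family holds one table per hash function: the `n_tables` largest
#' distinct primes at or below `table_size`. A k-mer is 2-bit encoded
#' (A=0, C=1, G=2, T=3, most-significant base first), canonicalized, passed
#' through a fixed 64-bit splitmix64-style finalizer, and reduced modulo
#' each prime. There is no randomized seeding: indices are identical across
#' runs, processes and platforms.
#'
#' @param n_tables Number of tables (hash functions); default 4.
#' @param table_size Approximate size of each table; the `n_tables` largest
#'   distinct primes `<= table_size` are used.
#' @return An object of class `hash_family` with element `table_sizes`.
#' @examples
#' hash_family(4, 1e5)$table_sizes
#' @export
hash_family <- function(n_tables = 4, table_size = 1e6) {
  n_tables <- as.integer(n_tables)
  if (is.na(n_tables) || n_tables < 1L) {
    stop("n_tables must be a positive integer", call. = FALSE)
  }
  table_size <- floor(as.numeric(table_size))
  if (is.na(table_size) || table_size < 3) {
    stop("table_size must be at least 3", call. = FALSE)
  }
  sizes <- numeric(0)
  p <- table_size
  while (length(sizes) < n_tables && p >= 3) {
    if (is_prime(p)) sizes <- c(sizes, p)
    p <- p - 1
  }
  if (length(sizes) < n_tables) {
    stop(sprintf("cannot find %d distinct primes <= %.0f", n_tables, table_size),
         call. = FALSE)
  }
  structure(list(table_sizes = sizes), class = "hash_family")
}

#' @export
print.hash_family <- function(x, ...) {
  cat(sprintf("<hash_family> %d tables, prime sizes: %s\n",
              length(x$table_sizes),
              paste(format(x$table_sizes, scientific = FALSE), collapse = ", ")))
  invisible(x)
}

resolve_family <- function(family, n_tables, table_size) {
  if (is.null(family)) family <- hash_family(n_tables, table_size)
  if (!inherits(family, "hash_family")) {
    stop("expected a 'hash_family' object; see hash_family()", call. = FALSE)
  }
  family
}

#' Reverse complement of DNA sequences
#'
#' Vectorised over `seqs`. Case-insensitive on input; output is upper-case.
#' `N` complements to `N`. Any character outside A, C, G, T, N raises an
#' invalid-alphabet error.
#'
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ATCG")
#' @export
reverse_complement <- function(seqs) {
  stopifnot(is.character(seqs))
  .rc_cpp(seqs)
}

#' Canonical form of k-mers
#'
#' Returns, for each k-mer, the lexicographically smaller of the k-mer and
#' its reverse complement when `spec$canonical` is set; otherwise the
#' (upper-cased) k-mer unchanged. Palindromic k-mers map to themselves.
#'
#' @param kmers Character vector of k-mers, each of length `spec$k`, with no
#'   ambiguous bases.
#' @param spec A [kmer_spec()].
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer("TTT", kmer_spec(3))
#' @export
canonical_kmer <- function(kmers, spec) {
  spec <- as_kmer_spec(spec)
  .canonical_cpp(kmers, spec$k, spec$canonical)
}

#' Enumerate the canonical k-mers of a sequence
#'
#' Slides a window of width `spec$k` across `seq` and reports each window's
#' canonical k-mer with its 1-based start position, in sequence order.
#' Windows covering any non-ACGT character are silently skipped — sequences
#' are never rewritten or "cleaned"; the number of skipped windows is
#' attached as the `skipped_windows` attribute. Sequences shorter than `k`
#' yield an empty result.
#'
#' @param seq A single DNA sequence (any length).
#' @param spec A [kmer_spec()].
#' @return A data.frame with columns `pos` (1-based start) and `kmer`, plus
#'   attribute `skipped_windows`.
#' @examples
#' iter_kmers("AANAA", kmer_spec(2))
#' @export
iter_kmers <- function(seq, spec) {
  spec <- as_kmer_spec(spec)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  res <- .iter_kmers_cpp(seq, spec$k, spec$canonical)
  out <- data.frame(pos = res$pos, kmer = res$kmer, stringsAsFactors = FALSE)
  attr(out, "skipped_windows") <- res$skipped
  out
}

#' Table indices of a k-mer under a hash family
#'
#' Deterministic 0-based index into each table: the canonical k-mer's 2-bit
#' encoding is mixed through the fixed 64-bit finalizer and reduced modulo
#' each table's prime size. A k-mer and its reverse complement map to
#' identical indices when `spec$canonical` is set.
#'
#' @param kmer A single k-mer of length `spec$k` (no ambiguous bases).
#' @param family A [hash_family()].
#' @param spec A [kmer_spec()].
#' @return Numeric vector of 0-based indices, one per table.
#' @examples
#' hash_indices("ACGTACGTAC", hash_family(4, 1e5), kmer_spec(10))
#' @export
hash_indices <- function(kmer, family, spec) {
  spec <- as_kmer_spec(spec)
  family <- resolve_family(family, NULL, NULL)
  stopifnot(is.character(kmer), length(kmer) == 1L)
  .hash_indices_cpp(kmer, spec$k, spec$canonical, family$table_sizes)
}
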