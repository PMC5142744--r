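#' Parameters for digital normalization
#'
#' Digital normalization is a streaming, lossy compression of a read set:
#' it keeps only the reads still needed to represent each locus at roughly
#' `cutoff` fold-coverage, using the median k-mer abundance of a read
#' (against the counts accumulated so far) as the coverage estimate.
#'
#' @param cutoff Desired coverage cutoff C (default 20). A read is kept
#'   while its median k-mer count is strictly below C. Must be at least 1
#'   and below the 8-bit counter cap (255).
#' @param spec A [kmer_spec()]; default `kmer_spec(20)`.
#' @param n_tables,table_size Parameters of the backing CountMin sketch.
#' @return An object of class `diginorm_params`.
#' @examples
#' diginorm_params(cutoff = 5, spec = kmer_spec(20))
#' @export
diginorm_params <- function(cutoff = 20, spec = kmer_spec(20),
                            n_tables = 4, table_size = 1e6) {
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) {
    stop("cutoff must be a positive integer", call. = FALSE)
  }
  if (cutoff >= 255L) {
    stop("cutoff must be below the 8-bit counter cap (255)", call. = FALSE)
  }
  spec <- as_kmer_spec(spec)
  structure(list(cutoff = cutoff, spec = spec,
                 n_tables = as.integer(n_tables),
                 table_size = as.numeric(table_size)),
            class = "diginorm_params")
}

#' Digital normalization by median k-mer abundance
#'
#' Single streaming pass over `reads`, in order. For each read the median
#' count of its valid k-mers is computed against the sketch *before* any
#' update. If the median is strictly below the cutoff the read is kept —
#' emitted byte-for-byte unmodified — and only then are its k-mers added
#' to the sketch; discarded reads contribute nothing. Reads with zero
#' valid k-mers (shorter than k, or all windows ambiguous) are dropped and
#' tallied separately rather than crashing the stream.
#'
#' Because kept reads replay exactly the sketch state they were accepted
#' under, re-running normalization on its own output with the same
#' parameters and a fresh sketch keeps 100% of reads (idempotence), and
#' raising the cutoff can only enlarge the kept set (monotonicity).
#'
#' @param reads A [sequence_records()] data.frame (or character vector of
#'   sequences).
#' @param params A [diginorm_params()].
#' @param sketch Optional pre-loaded [countmin_sketch()] for resumable
#'   runs; defaults to a fresh sketch built from `params`. Its k-mer spec
#'   must match `params$spec`.
#' @return A list of class `diginorm_result` with elements `kept` (records,
#'   order and content preserved), `sketch` (the backing sketch after the
#'   pass) and `report` (class `diginorm_report`: `n_seen`, `n_kept`,
#'   `n_discarded`, `n_skipped_no_kmers`).
#' @examples
#' reads <- sequence_records(paste0("r", 1:10), rep(strrep("A", 8), 10))
#' res <- normalize_by_median(reads, diginorm_params(3, kmer_spec(4),
#'                                                   table_size = 1e4))
#' res$report
#' @export
normalize_by_median <- function(reads, params, sketch = NULL) {
  if (!inherits(params, "diginorm_params")) {
    stop("expected 'diginorm_params'; see diginorm_params()", call. = FALSE)
  }
  if (is.character(reads)) {
    reads <- sequence_records(as.character(seq_along(reads)), reads)
  }
  stopifnot(is.data.frame(reads))
  if (is.null(sketch)) {
    sketch <- countmin_sketch(params$spec, n_tables = params$n_tables,
                              table_size = params$table_size)
  } else {
    sketch <- as_cms(sketch)
    check_spec_match(sketch$spec, params$spec, "the supplied sketch")
  }
  n <- nrow(reads)
  keep <- logical(n)
  n_skipped <- 0L
  C <- params$cutoff
  k <- params$spec$k
  for (i in seq_len(n)) {
    seq_i <- reads$sequence[[i]]
    counts <- .cms_kmer_counts(sketch$ptr, seq_i)$count
    m <- length(counts)
    if (m == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    med <- sort.int(counts)[m %/% 2L + 1L]
    if (med < C) {
      keep[[i]] <- TRUE
      .cms_consume(sketch$ptr, seq_i)
    }
  }
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(n_seen = n, n_kept = sum(keep),
                           n_discarded = n - sum(keep) - n_skipped,
                           n_skipped_no_kmers = n_skipped),
                      class = "diginorm_report")
  structure(list(kept = kept, sketch = sketch, report = report),
            class = "diginorm_result")
}

#' @export
print.diginorm_report <- function(x, ...) {
  cat(sprintf("<diginorm_report> seen %d | kept %d (%.1f%%) | discarded %d | no-kmer %d\n",
              x$n_seen, x$n_kept,
              if (x$n_seen > 0) 100 * x$n_kept / x$n_seen else 0,
              x$n_discarded, x$n_skipped_no_kmers))
  invisible(x)
}

#' @export
print.diginorm_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Retained coverage of a normalized read set
#'
#' Total kept bases divided by the reference length: the fold-coverage
#' still represented after normalization. Used to verify that the lossy
#' compression retains roughly cutoff-fold coverage of each locus.
#'
#' @param kept A [sequence_records()] data.frame (e.g. `$kept` from
#'   [normalize_by_median()]).
#' @param reference_length Length of the underlying reference in bases
#'   (> 0).
#' @return A single numeric fold-coverage.
#' @export
estimate_retained_coverage <- function(kept, reference_length) {
  stopifnot(is.data.frame(kept), reference_length > 0)
  if (nrow(kept) == 0L) return(0)
  sum(nchar(kept$sequence)) / reference_length
}
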