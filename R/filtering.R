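#' Parameters for abundance trimming
#'
#' @param min_count Abundance cutoff (default 2): a read is truncated at
#'   its first k-mer whose counted abundance falls below this value —
#'   k-mers seen only once in deep data are overwhelmingly sequencing
#'   errors.
#' @param min_length Minimum surviving read length (default: the sketch's
#'   k); shorter survivors are discarded outright.
#' @return An object of class `trim_params`.
#' @examples
#' trim_params(min_count = 2, min_length = 20)
#' @export
trim_params <- function(min_count = 2, min_length = NULL) {
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) {
    stop("min_count must be a positive integer", call. = FALSE)
  }
  structure(list(min_count = min_count,
                 min_length = if (is.null(min_length)) NULL
                              else as.integer(min_length)),
            class = "trim_params")
}

resolve_trim <- function(params, spec) {
  if (!inherits(params, "trim_params")) {
    stop("expected 'trim_params'; see trim_params()", call. = FALSE)
  }
  if (is.null(params$min_length)) params$min_length <- spec$k
  if (params$min_length < spec$k) {
    stop(sprintf("min_length (%d) must be at least k (%d)",
                 params$min_length, spec$k), call. = FALSE)
  }
  params
}

#' Trim a read at its first low-abundance k-mer
#'
#' Scans the read's valid k-mers in order against a sketch already loaded
#' with the full data set. At the first position whose count falls below
#' `min_count`, the read is truncated to end with the last base *before*
#' that k-mer's window (its first `i + k - 2` bases for first low 1-based
#' position `i`), and the quality string is truncated identically. Reads
#' whose every k-mer passes are returned byte-identical; survivors shorter
#' than `min_length` are discarded. Windows containing ambiguous bases
#' carry no count and are not trim triggers.
#'
#' @param read A single-row [sequence_records()] data.frame.
#' @param sketch A [countmin_sketch()] loaded with the full data set.
#' @param params A [trim_params()].
#' @return The (possibly truncated) single-row records data.frame, or
#'   `NULL` as the discard signal.
#' @export
trim_low_abundance <- function(read, sketch, params) {
  sketch <- as_cms(sketch)
  stopifnot(is.data.frame(read), nrow(read) == 1L)
  params <- resolve_trim(params, sketch$spec)
  res <- .cms_kmer_counts(sketch$ptr, read$sequence[[1]])
  low <- which(res$count < params$min_count)
  if (length(low) == 0L) {
    return(read)
  }
  keep_len <- res$pos[[low[[1]]]] + sketch$spec$k - 2L
  if (keep_len < params$min_length) {
    return(NULL)
  }
  read$sequence[[1]] <- substr(read$sequence[[1]], 1L, keep_len)
  if (!is.na(read$quality[[1]])) {
    read$quality[[1]] <- substr(read$quality[[1]], 1L, keep_len)
  }
  read
}

#' Abundance-trim a whole read set
#'
#' Applies [trim_low_abundance()] to every read (two-pass design: count
#' the full data set into `sketch` first, then trim), emitting survivors
#' in input order.
#'
#' @param reads A [sequence_records()] data.frame.
#' @param sketch A [countmin_sketch()] loaded with the full data set.
#' @param params A [trim_params()].
#' @return A list of class `filter_result`: `kept` (records), and `report`
#'   with `n_seen`, `n_trimmed` (emitted shorter than they arrived),
#'   `n_discarded` (dropped entirely).
#' @export
filter_abund <- function(reads, sketch, params) {
  sketch <- as_cms(sketch)
  stopifnot(is.data.frame(reads))
  params <- resolve_trim(params, sketch$spec)
  n <- nrow(reads)
  out <- vector("list", n)
  n_trimmed <- 0L
  n_discarded <- 0L
  for (i in seq_len(n)) {
    r <- trim_low_abundance(reads[i, , drop = FALSE], sketch, params)
    if (is.null(r)) {
      n_discarded <- n_discarded + 1L
    } else {
      if (nchar(r$sequence[[1]]) < nchar(reads$sequence[[i]])) {
        n_trimmed <- n_trimmed + 1L
      }
      out[[i]] <- r
    }
  }
  kept <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(kept)) kept <- empty_records()
  rownames(kept) <- NULL
  class(kept) <- c("sequence_records", "data.frame")
  structure(list(kept = kept,
                 report = list(n_seen = n, n_trimmed = n_trimmed,
                               n_discarded = n_discarded)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> seen %d | trimmed %d | discarded %d | emitted %d\n",
              x$report$n_seen, x$report$n_trimmed, x$report$n_discarded,
              nrow(x$kept)))
  invisible(x)
}

#' Mean-quality read filter
#'
#' Minimal quality-control stage: drops reads whose mean Phred quality is
#' below `min_mean_q` or whose length is below `min_len`. Sequences are
#' never modified — reads pass or fail whole. Qualities are Phred+33;
#' characters outside the printable Phred+33 range (`!`..`~`) are rejected
#' loudly rather than reinterpreted.
#'
#' @param reads A [sequence_records()] data.frame with qualities (FASTQ).
#'   FASTA-style records (no qualities) are a configuration error when
#'   `min_mean_q` is set.
#' @param min_mean_q Minimum mean Phred quality (default 0: length-only).
#' @param min_len Minimum read length (default 1).
#' @return The kept [sequence_records()], in input order.
#' @export
quality_filter <- function(reads, min_mean_q = 0, min_len = 1) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) return(reads)
  if (min_mean_q > 0 && any(is.na(reads$quality))) {
    stop("quality filtering with min_mean_q requires FASTQ input: records have no quality strings",
         call. = FALSE)
  }
  keep_len <- nchar(reads$sequence) >= min_len
  if (min_mean_q > 0) {
    mean_q <- vapply(reads$quality, function(q) {
      ph <- utf8ToInt(q) - 33L
      if (any(ph < 0L | ph > 93L)) {
        stop("quality string contains characters outside the Phred+33 range ('!'..'~')",
             call. = FALSE)
      }
      mean(ph)
    }, numeric(1), USE.NAMES = FALSE)
    keep <- keep_len & mean_q >= min_mean_q
  } else {
    keep <- keep_len
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
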