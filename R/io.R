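#' Construct a set of sequence records
#'
#' Records are a plain data.frame with columns `id`, `desc`, `sequence` and
#' `quality` (class `sequence_records`). `quality` is `NA` for FASTA-style
#' records and must match the sequence length character-for-character when
#' present. Sequence content is stored exactly as given: the record layer
#' never case-folds, never strips ambiguous bases, never rewrites anything
#' — any interpretation (upper-casing, skipping N windows) happens only at
#' k-mer extraction.
#'
#' @param id Character vector of record identifiers (no leading `>`/`@`).
#' @param sequence Character vector of sequences (non-empty).
#' @param quality Optional character vector of Phred+33 quality strings.
#' @param desc Optional character vector of free-text descriptions.
#' @return A `sequence_records` data.frame.
#' @examples
#' sequence_records("r1", "ACGT", "IIII")
#' @export
sequence_records <- function(id, sequence, quality = NA_character_,
                             desc = NA_character_) {
  n <- length(sequence)
  out <- data.frame(id = as.character(id),
                    desc = rep_len(as.character(desc), n),
                    sequence = as.character(sequence),
                    quality = rep_len(as.character(quality), n),
                    stringsAsFactors = FALSE)
  bad <- which(!is.na(out$quality) & nchar(out$quality) != nchar(out$sequence))
  if (length(bad)) {
    stop(sprintf("record '%s': quality length %d does not match sequence length %d",
                 out$id[bad[[1]]], nchar(out$quality[bad[[1]]]),
                 nchar(out$sequence[bad[[1]]])), call. = FALSE)
  }
  if (any(!nzchar(out$sequence))) {
    stop("records must have non-empty sequences", call. = FALSE)
  }
  class(out) <- c("sequence_records", "data.frame")
  out
}

#' @export
print.sequence_records <- function(x, ...) {
  cat(sprintf("<sequence_records> %d records (%s)\n", nrow(x),
              if (all(is.na(x$quality))) "FASTA, no qualities" else "with qualities"))
  NextMethod()
}

empty_records <- function() {
  sequence_records(character(0), character(0), character(0), character(0))
}

open_text <- function(path, mode) {
  # gzfile() reads plain files transparently; on write, compress iff the
  # filename asks for it.
  if (mode == "rt") {
    gzfile(path, "rt")
  } else if (grepl("\\.gz$", path)) {
    gzfile(path, "wt")
  } else {
    file(path, "wt")
  }
}

split_header <- function(line) {
  header <- sub("^.", "", line)
  sp <- regexpr("[ \t]", header)
  if (sp < 0) {
    c(header, NA_character_)
  } else {
    c(substr(header, 1L, sp - 1L), substr(header, sp + 1L, nchar(header)))
  }
}

#' Read FASTA or FASTQ records
#'
#' Auto-detects the format from the first byte (`>` FASTA, `@` FASTQ) and
#' decompresses gzip transparently. Multi-line FASTA is supported; FASTQ
#' must be the common 4-line dialect (multi-line FASTQ is rejected with an
#' error rather than guessed at). Sequences are returned byte-for-byte as
#' they appear in the file. An empty file yields zero records, not an
#' error; malformed records raise a parse error naming the record id and
#' line number.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @return A [sequence_records()] data.frame, with attribute `format`
#'   (`"fasta"` or `"fastq"`).
#' @export
read_records <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    out <- empty_records()
    attr(out, "format") <- NA_character_
    return(out)
  }
  first <- substr(lines[[1]], 1L, 1L)
  if (first == ">") {
    out <- parse_fasta(lines)
    attr(out, "format") <- "fasta"
  } else if (first == "@") {
    out <- parse_fastq(lines)
    attr(out, "format") <- "fastq"
  } else {
    stop(sprintf("cannot detect format of '%s': first byte is '%s', expected '>' (FASTA) or '@' (FASTQ)",
                 path, first), call. = FALSE)
  }
  out
}

parse_fasta <- function(lines) {
  is_header <- startsWith(lines, ">")
  if (!is_header[[1]]) {
    stop("parse error at line 1: FASTA must start with '>'", call. = FALSE)
  }
  idx <- which(is_header)
  headers <- t(vapply(lines[idx], split_header, character(2), USE.NAMES = FALSE))
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- character(length(idx))
  for (i in seq_along(idx)) {
    if (ends[[i]] < idx[[i]] + 1L) {
      stop(sprintf("parse error at line %d: record '%s' has no sequence lines",
                   idx[[i]], headers[i, 1]), call. = FALSE)
    }
    seqs[[i]] <- paste(lines[(idx[[i]] + 1L):ends[[i]]], collapse = "")
  }
  if (any(!nzchar(seqs))) {
    j <- which(!nzchar(seqs))[[1]]
    stop(sprintf("parse error at line %d: record '%s' has an empty sequence",
                 idx[[j]], headers[j, 1]), call. = FALSE)
  }
  sequence_records(headers[, 1], seqs, NA_character_, headers[, 2])
}

parse_fastq <- function(lines) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("parse error at line %d: FASTQ line count %d is not a multiple of 4 (only the 4-line dialect is supported)",
                 n, n), call. = FALSE)
  }
  at <- seq(1L, n, by = 4L)
  heads <- lines[at]
  seqs <- lines[at + 1L]
  plus <- lines[at + 2L]
  quals <- lines[at + 3L]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected '@' header, got '%s' (multi-line FASTQ is not supported)",
                 at[bad[[1]]], substr(heads[bad[[1]]], 1L, 20L)), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected '+' separator (multi-line FASTQ is not supported)",
                 at[bad[[1]]] + 2L), call. = FALSE)
  }
  headers <- t(vapply(heads, split_header, character(2), USE.NAMES = FALSE))
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: record '%s' has quality length %d but sequence length %d",
                 at[bad[[1]]] + 3L, headers[bad[[1]], 1],
                 nchar(quals[bad[[1]]]), nchar(seqs[bad[[1]]])), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    j <- which(!nzchar(seqs))[[1]]
    stop(sprintf("parse error at line %d: record '%s' has an empty sequence",
                 at[[j]] + 1L, headers[j, 1]), call. = FALSE)
  }
  sequence_records(headers[, 1], seqs, quals, headers[, 2])
}

#' Write records as FASTA or FASTQ
#'
#' The format defaults to FASTQ when every record carries a quality string
#' and FASTA otherwise; requesting FASTQ output for records lacking
#' qualities is an error (qualities are never invented). FASTA sequences
#' are wrapped at 80 columns; output is gzip-compressed when `path` ends in
#' `.gz`. Sequences and qualities are written byte-for-byte.
#'
#' @param records A [sequence_records()] data.frame.
#' @param path Output path.
#' @param format `"fasta"`, `"fastq"`, or `NULL` to infer from the records.
#' @return The number of records written, invisibly.
#' @export
write_records <- function(records, path, format = NULL) {
  stopifnot(is.data.frame(records))
  if (length(format) == 1L && is.na(format)) format <- NULL
  if (is.null(format)) {
    format <- if (nrow(records) > 0L && all(!is.na(records$quality))) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  con <- open_text(path, "wt")
  on.exit(close(con))
  head_of <- function(prefix) {
    ifelse(is.na(records$desc), paste0(prefix, records$id),
           paste0(prefix, records$id, " ", records$desc))
  }
  if (nrow(records) == 0L) {
    return(invisible(0L))
  }
  if (format == "fastq") {
    if (any(is.na(records$quality))) {
      stop("cannot write FASTQ: records lack quality strings", call. = FALSE)
    }
    writeLines(rbind(head_of("@"), records$sequence, "+", records$quality), con)
  } else {
    for (i in seq_len(nrow(records))) {
      writeLines(head_of(">")[[i]], con)
      s <- records$sequence[[i]]
      starts <- seq(1L, nchar(s), by = 80L)
      writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
    }
  }
  invisible(nrow(records))
}
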