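#' Run the chained pre-filtering pipeline
#'
#' Takes a read file through the canonical pre-assembly stages in order:
#' quality filter, k-mer counting, abundance trimming, digital
#' normalization. Each stage is executed through the command-line surface
#' ([run_command()]) so the pipeline exercises exactly what a shell user
#' runs; a nonzero stage exit aborts the pipeline with earlier outputs
#' preserved. All stages are deterministic, so re-running in a clean
#' directory with identical input bytes and flags reproduces every output
#' byte-for-byte.
#'
#' Stage outputs in `workdir`: `s1_quality.fq` (or `.fa`), `counts.mkm`,
#' `s2_trimmed.fq`, `s3_normalized.fq`, and `summary.tsv` with per-stage
#' read counts and retention fractions. "Approximately the expected
#' results" is made testable by [check_pipeline_bands()], which compares
#' retentions against tolerance bands shipped in a versioned config file.
#'
#' @param input Path to a FASTA/FASTQ file.
#' @param workdir Directory for stage outputs (created if needed).
#' @param k K-mer length (default 20).
#' @param cutoff Digital-normalization coverage cutoff (default 20).
#' @param min_count Abundance-trim cutoff (default 2).
#' @param min_mean_q Minimum mean Phred quality (default 30).
#' @param min_len Minimum read length for the quality stage (default `k`).
#' @param n_tables,table_size Sketch geometry for counting stages.
#' @return A list of class `pipeline_result`: `summary` (data.frame with
#'   columns `stage`, `n_in`, `n_out`, `retention`), `bands` (the band
#'   check from [check_pipeline_bands()]), and `workdir`, invisibly.
#' @export
run_acceptance_pipeline <- function(input, workdir, k = 20, cutoff = 20,
                                    min_count = 2, min_mean_q = 30,
                                    min_len = NULL, n_tables = 4,
                                    table_size = 1e6) {
  if (!file.exists(input)) {
    stop(sprintf("cannot read input file '%s'", input), call. = FALSE)
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(min_len)) min_len <- k
  fmt <- attr(read_records(input), "format")
  ext <- if (identical(fmt, "fasta")) "fa" else "fq"
  f1 <- file.path(workdir, paste0("s1_quality.", ext))
  fsk <- file.path(workdir, "counts.mkm")
  f2 <- file.path(workdir, paste0("s2_trimmed.", ext))
  f3 <- file.path(workdir, paste0("s3_normalized.", ext))

  stage <- function(label, argv) {
    status <- suppressMessages(run_command(argv))
    if (status != 0L) {
      stop(sprintf("pipeline stage '%s' failed with exit status %d; earlier outputs kept in '%s'",
                   label, status, workdir), call. = FALSE)
    }
  }
  n_of <- function(path) nrow(read_records(path))

  n0 <- n_of(input)
  qf_args <- c("quality-filter", "--min-len", min_len, "-o", f1, input)
  if (identical(fmt, "fastq")) {
    qf_args <- c("quality-filter", "--min-mean-q", min_mean_q,
                 "--min-len", min_len, "-o", f1, input)
  }
  stage("quality-filter", as.character(qf_args))
  n1 <- n_of(f1)

  stage("count", as.character(c("count", "-k", k, "-N", n_tables,
                                "-x", format(table_size, scientific = FALSE),
                                "-o", fsk, f1)))

  stage("filter-abund", as.character(c("filter-abund", "-C", min_count,
                                       fsk, f1, "-o", f2)))
  n2 <- n_of(f2)

  stage("normalize-by-median",
        as.character(c("normalize-by-median", "-C", cutoff, "-k", k,
                       "-N", n_tables,
                       "-x", format(table_size, scientific = FALSE),
                       "-o", f3, f2)))
  n3 <- n_of(f3)

  retention <- function(out, inn) if (inn > 0) out / inn else 1
  summary <- data.frame(
    stage = c("quality-filter", "filter-abund", "normalize-by-median"),
    n_in = c(n0, n1, n2),
    n_out = c(n1, n2, n3),
    retention = c(retention(n1, n0), retention(n2, n1), retention(n3, n2)),
    stringsAsFactors = FALSE)
  write_summary_tsv(summary, file.path(workdir, "summary.tsv"))
  bands <- check_pipeline_bands(summary)
  invisible(structure(list(summary = summary, bands = bands,
                           workdir = workdir),
                      class = "pipeline_result"))
}

write_summary_tsv <- function(summary, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("stage\tn_in\tn_out\tretention",
               sprintf("%s\t%d\t%d\t%.6f", summary$stage, summary$n_in,
                       summary$n_out, summary$retention)), con)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$bands)) {
    cat(sprintf("band check: %s\n",
                if (all(x$bands$ok)) "all stages within bands"
                else paste("OUT OF BAND:",
                           paste(x$bands$stage[!x$bands$ok], collapse = ", "))))
  }
  invisible(x)
}

#' Check per-stage retention against shipped tolerance bands
#'
#' The expected per-stage retention fractions for a default 50-fold
#' simulated run — with tolerances wide enough to absorb sampling noise —
#' live in `inst/extdata/pipeline-bands.tsv` (columns `stage`,
#' `min_retention`, `max_retention`). This function compares a pipeline
#' summary against them. Bands travel with the package version: they are
#' part of the command-line contract's "approximately expected results".
#'
#' @param summary The `summary` data.frame from [run_acceptance_pipeline()].
#' @param bands_file Path to a bands TSV; defaults to the shipped file.
#' @return A data.frame with columns `stage`, `retention`, `min_retention`,
#'   `max_retention`, `ok`. Stages that saw zero input reads are marked ok
#'   (an empty run is within any band).
#' @export
check_pipeline_bands <- function(summary,
                                 bands_file = system.file("extdata",
                                                          "pipeline-bands.tsv",
                                                          package = "kmersieve")) {
  bands <- utils::read.delim(bands_file, stringsAsFactors = FALSE)
  m <- merge(summary, bands, by = "stage", sort = FALSE)
  m$ok <- (m$n_in == 0) |
    (m$retention >= m$min_retention & m$retention <= m$max_retention)
  m[, c("stage", "retention", "min_retention", "max_retention", "ok")]
}
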