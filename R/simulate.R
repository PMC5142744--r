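#' Simulate a random genome
#'
#' Uniform i.i.d. ACGT string, reproducible per seed. The generator saves
#' and restores the caller's RNG state, so simulations are pure functions
#' of their parameters and seed.
#'
#' @param length Genome length in bases (>= 1).
#' @param seed Integer seed.
#' @return A single DNA string.
#' @examples
#' substr(simulate_genome(50, seed = 1), 1, 10)
#' @export
simulate_genome <- function(length, seed) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate shotgun reads from a genome
#'
#' Draws `round(coverage * genome_length / read_length)` reads at uniform
#' random start positions on the forward or reverse-complement strand
#' (probability 0.5 each), substituting each base with probability
#' `error_rate` by a uniformly chosen *different* base — substitutions
#' only, no indels. Qualities are constant Q40 (`I`). Deterministic per
#' seed. This emulates the error-bearing, coverage-redundant short-read
#' inputs the pre-filtering algorithms are designed for; it does not model
#' quality decay along reads, GC bias or indels.
#'
#' @param genome A single DNA string.
#' @param read_length Read length in bases (`<=` genome length).
#' @param coverage Target fold-coverage (> 0).
#' @param error_rate Per-base substitution probability in \[0, 1).
#' @param seed Integer seed.
#' @return A [sequence_records()] data.frame; each record's `desc` notes
#'   the 1-based start position and strand of origin.
#' @examples
#' g <- simulate_genome(200, seed = 1)
#' simulate_reads(g, read_length = 50, coverage = 2, error_rate = 0, seed = 2)
#' @export
simulate_reads <- function(genome, read_length, coverage, error_rate = 0,
                           seed = 1) {
  stopifnot(is.character(genome), length(genome) == 1L)
  G <- nchar(genome)
  read_length <- as.integer(read_length)
  stopifnot(read_length >= 1L, read_length <= G,
            coverage > 0, error_rate >= 0, error_rate < 1)
  n_reads <- round(coverage * G / read_length)
  if (n_reads == 0L) return(empty_records())
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    starts <- sample.int(G - read_length + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_length - 1L)
    rev <- strands == "-"
    if (any(rev)) seqs[rev] <- reverse_complement(seqs[rev])
    if (error_rate > 0) {
      n_err <- stats::rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(read_length, n_err[[i]])
        chars <- strsplit(seqs[[i]], "")[[1]]
        for (p in pos) {
          chars[[p]] <- sample(setdiff(bases, chars[[p]]), 1L)
        }
        seqs[[i]] <- paste(chars, collapse = "")
      }
    }
    sequence_records(
      id = sprintf("read%06d", seq_len(n_reads)),
      sequence = seqs,
      quality = strrep("I", read_length),
      desc = sprintf("pos=%d strand=%s", starts, strands)
    )
  })
}
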