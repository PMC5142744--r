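# Deterministic coverage fixtures for the trimming tests.
#
# Uniform random read starts systematically undersample the first and last
# k-1 genome positions, so "every true k-mer appears at least twice" does
# not hold for a purely random simulation at moderate coverage. tile_reads
# lays down two staggered deterministic tilings (both anchored at the first
# and the last possible start), which guarantees the >= 2x premise for
# every genomic k-mer; random simulated reads are added on top for
# realistic coverage fluctuation.
tile_reads <- function(genome, read_length, step) {
  G <- nchar(genome)
  last <- G - read_length + 1L
  t1 <- unique(c(seq(1L, last, by = step), last))
  t2 <- unique(c(1L, seq(1L + step %/% 2L, last, by = step), last))
  starts <- c(t1, t2)
  seqs <- substring(genome, starts, starts + read_length - 1L)
  sequence_records(id = sprintf("tile%04d", seq_along(starts)),
                   sequence = seqs,
                   quality = strrep("I", read_length),
                   desc = sprintf("pos=%d strand=+", starts))
}

# Plant one substitution per selected read at 1-based position `pos`,
# switching to a deterministic different base.
plant_substitutions <- function(reads, which, pos, seed) {
  bases <- c("A", "C", "G", "T")
  set.seed(seed)
  for (i in which) {
    old <- substr(reads$sequence[[i]], pos, pos)
    new <- sample(setdiff(bases, old), 1L)
    substr(reads$sequence[[i]], pos, pos) <- new
  }
  reads
}
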