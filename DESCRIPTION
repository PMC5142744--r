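Package: kmersieve
Title: K-mer Counting Sketches and Streaming Read Pre-Filtering
Version: 1.0.0
Authors@R: person("kmersieve", "developers", role = c("aut", "cre"),
    email = "maintainers@kmersieve.example.org")
Description: Probabilistic data structures and streaming algorithms for
    pre-filtering large DNA sequencing read sets before mapping or assembly.
    Provides approximate k-mer abundance counting with a CountMin sketch
    (overcount-only, 8-bit saturating counters), an approximate k-mer
    presence graph (Bloom-filter node set with implicit edges between
    k-mers overlapping by k-1 bases) supporting connectivity queries and
    read partitioning, streaming digital normalization (keep a read only
    while its median k-mer abundance is below a coverage cutoff), and
    abundance-based error trimming. Includes FASTA/FASTQ readers and
    writers that never rewrite sequence content, a seeded read simulator
    for testing, and a semantically versioned command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
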