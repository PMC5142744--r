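---
title: "Methods: sketch-based k-mer counting and streaming read pre-filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sketch-based k-mer counting and streaming read pre-filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersieve)
```

# The problem

Short-read sequencing projects routinely produce far more data than
downstream tools (mappers, assemblers) need or can hold in memory. Much of
that volume is redundancy — the same genomic locus sampled tens or hundreds
of times — plus a long tail of erroneous k-mers created by sequencing
errors. kmersieve pre-filters read sets *before* those expensive steps,
using fixed-memory probabilistic data structures over k-mers (substrings of
length k, here 1 ≤ k ≤ 32 so a k-mer packs into a 64-bit word at 2 bits
per base).

Four capabilities share one foundation:

* approximate k-mer **counting** with a CountMin sketch;
* an approximate k-mer **presence graph** (Bloom-filter node set with
  implicit edges between k-mers overlapping by k−1) for connectivity
  queries and read partitioning;
* **digital normalization**, a single-pass lossy compression that keeps a
  read only while the median abundance of its k-mers is still below a
  coverage cutoff C;
* **abundance trimming**, truncating reads at their first low-abundance
  k-mer (a signature of sequencing error in deep data).

# K-mer conventions

**Canonicalization.** By default each k-mer is identified with its reverse
complement and represented by the lexicographically smaller of the two, so
both strands of a locus accumulate in one counter. Palindromic k-mers map
to themselves. Lower-case input is accepted and upper-cased *at k-mer
extraction only* — the record layer never rewrites sequence bytes.

**Ambiguity handling.** Windows containing any non-ACGT character are
skipped and tallied, never "repaired": silently rewriting user data (for
example deleting ambiguous nucleotides) is a biologically inappropriate
transformation, and this package's I/O contract forbids it end to end.
Reads whose every window is ambiguous (or that are shorter than k) flow
through the streaming operations as explicit "no k-mer" tallies rather than
errors.

**Hashing.** A k-mer is 2-bit encoded (A=0, C=1, G=2, T=3,
most-significant base first, so numeric order equals lexicographic order),
canonicalized, mixed through a fixed splitmix64-style 64-bit finalizer, and
reduced modulo each table's prime size. One mix, N distinct prime moduli:
the table addresses are deterministic across runs, processes and platforms
(golden-value tests pin them), which is what makes sketch files and seeded
pipelines exactly reproducible. There is no randomized hash seeding
anywhere.

# The CountMin sketch

`countmin_sketch(spec, n_tables, table_size)` allocates N tables whose
sizes are the N largest distinct primes at or below the requested size
(default N = 4). Adding a k-mer increments one 8-bit saturating cell per
table; a query returns the minimum over its cells. Collisions can only
inflate a count, so estimates are **overcount-only**: for every k-mer,
`count(x) ≥ min(true(x), 255)`, with equality whenever at least one table
held no collision for x. At the occupancies used in this package's tests
(< 1%), the probability that all N cells collide is roughly the product of
the occupancies — about 10⁻⁸ at 1% across four tables — so estimates agree
with an exact dictionary counter for ≥ 99% of distinct k-mers by a wide
margin. `fp_rate()` reports that occupancy product; an empirical probe of
never-inserted k-mers reproduces it within Monte-Carlo noise.

Counters saturate at 255 by default. The thresholds these counts feed
(coverage cutoffs of 5–20, trim cutoffs of 2) sit far below the cap, so
wider counters would buy nothing here; saturation behavior is tested
explicitly.

**The median statistic.** `median_count()` summarises a read's count
spectrum. The median of a read's k-mer counts is a robust estimator of the
coverage of the read's locus: unlike the mean it is insensitive both to
the few inflated counts a collision or a genomic repeat can contribute and
to the rare k-mers a sequencing error creates near the read's ends. The
convention is fixed as the *upper median* —
element ⌊n/2⌋ (0-based) of the sorted list — and the reported spread is the
population standard deviation (0 for a single k-mer). Both choices are
arbitrary but frozen and tested; changing either would silently shift
normalization behavior.

# Digital normalization

`normalize_by_median(reads, diginorm_params(cutoff = C, ...))` makes one
pass, in order. For each read:

1. the median count of its valid k-mers is computed against the sketch
   **before any update**;
2. if `median < C` (strictly), the read is kept — emitted byte-for-byte —
   and only then are its k-mers added;
3. otherwise nothing is added and the read is dropped.

Querying before updating, and updating only for kept reads, is what makes
the operation **idempotent**: a kept read, replayed over the kept stream
alone, encounters exactly the sketch state it was accepted under, so a
second pass keeps 100% of reads. The strict inequality is likewise fixed
and encoded in tests (the hand-traceable example: ten copies of an 8-mer
read at k = 4, C = 3 keep exactly the first copy, which alone pushes the
median to 5 ≥ 3).

**What monotonicity holds.** For reads of a single locus the kept set is
exactly nested across cutoffs. Across loci it is *nearly* nested: under a
higher cutoff more early reads are kept, so a later read spanning both a
deep and a shallow locus can see a median above a bar it passed at the
lower cutoff. Empirically 1–2% of kept reads flip on 30× simulations; the
kept *count* remains monotone in C. The tests encode exactly these
statements rather than the stronger (false) set-inclusion claim.

**Short-read policy.** Reads with zero valid k-mers are dropped and tallied
in `n_skipped_no_kmers` — they carry no evidence either way, and passing
them through would make the output depend on k in a surprising way.
Paired-end awareness is out of scope; reads are independent.

# The node graph and partitioning

`node_graph()` stores the k-mer set in N bit tables over the same hash
family: membership has **no false negatives**, and false positives at the
occupancy product rate. Edges are implicit: the at most 8 k-mers
overlapping a node by k−1 bases (4 right extensions, 4 left), filtered by
membership. `connected_component()` is breadth-first with lexicographic
ordering within each frontier (so traversals reproduce exactly) and a
`max_nodes` cap with a truncation flag.

`partition_reads()` assigns two reads the same dense partition id exactly
when their k-mers lie in one traversal component: union-find over the
k-mers discovered by traversal, each read additionally linking its own
k-mers (so a read spans its own ambiguity gaps). Ids are numbered in
first-seen read order; reads without k-mers get the sentinel 0. Bloom
false positives can in principle bridge two true components; tests and the
shipped defaults keep occupancy low enough (< 1%) that an exact-set
union-find oracle (via igraph) agrees on every tested case. Partitioning
is invariant under read order up to relabeling.

# Abundance trimming and quality filtering

`filter_abund()` is deliberately two-pass: count the *full* data set into a
sketch, then truncate each read just before its first window whose count
falls below `min_count` (default 2). Truncate-don't-split keeps the
contract simple; survivors shorter than `min_length` (default k) are
discarded. Windows with ambiguous bases carry no count and are not trim
triggers. Because counts are overcount-only, trimming can only ever be
*too lenient* in the rare all-tables-collision case, never too aggressive.

`quality_filter()` is the minimal quality-control stage the pipeline
needs: drop (never modify) reads below a mean Phred+33 quality or length
threshold. Characters outside `!`..`~` are rejected loudly rather than
reinterpreted as another encoding.

# I/O contract

FASTA and FASTQ (4-line dialect only; multi-line FASTQ is refused rather
than guessed), plain or gzip, auto-detected from the first byte. Parsing
preserves sequence and quality bytes exactly — no case folding, no
alphabet coercion — and parse errors name the record id and line number.
FASTQ round trips are byte-identical; FASTA output wraps at 80 columns.
Sketch and graph files share a validated binary container (magic `MKM1` /
`MNG1`, version, k, canonical flag, table count, then per-table prime size
and raw payload); corrupt or truncated files fail naming the offending
field, and a loaded structure refuses to serve a mismatched k.

# The synthetic-data generator

`simulate_genome()` draws uniform i.i.d. ACGT; `simulate_reads()` draws
`round(coverage × G / L)` reads at uniform starts, forward or
reverse-complement strand with probability 0.5 each, substituting each base
with probability `error_rate` by a uniformly chosen different base;
qualities are constant Q40. Both are pure functions of their parameters
and seed, and restore the caller's RNG state.

This emulates what the pre-filters consume — coverage-redundant,
error-bearing short reads from both strands — and deliberately omits
quality decay along reads, GC and coverage bias, indels, and paired-end
structure. Passing tests therefore demonstrate algorithmic correctness
under a clean substitution-error model, not robustness to every artifact
of real instruments; the operations themselves never assume anything about
the error model beyond "errors create rare k-mers".

One systematic property of uniform *linear* read sampling matters for the
trimming tests: the first and last k−1 genome positions are covered by
far fewer reads than interior positions, so "every true k-mer appears at
least twice" fails near the termini with non-negligible probability at
moderate coverage. The planted-error fixtures therefore lay down two
staggered deterministic read tilings (both anchored at the first and last
possible start), which guarantee the ≥ 2× premise by construction, and add
random reads on top for realistic fluctuation. Errors are planted only
into the random portion — corrupting a tiling read would break the very
premise the tiling provides.

# Study conditions used by the automated checks

The test suite and `scripts/acceptance.R` fix these problem sizes: oracle
comparisons run 20 seeded simulations of a 10 kb genome at 10–50× with
k = 20 and four tables of ~4·10⁶ cells (occupancy < 1%, so the exact
dictionary counter is the reference); normalization properties use 50×
coverage of 10 kb at C = 5 and C = 20; partitioning uses two independent
2 kb genomes at 15× (k-mer-disjoint with overwhelming probability, and
asserted disjoint before use — 15× keeps the chance of a coverage gap
longer than L−k per genome below ~0.1%, so each genome forms one
component); trimming plants three substitutions at 20× effective coverage.
These sizes make each check run in seconds while keeping every collision
and sampling-noise bound far from its threshold.

# Command-line surface and versioning

The CLI (`exec/kmersieve`, a thin wrapper over `run_command()`) carries the
package's compatibility promise: within a major version series no flag is
removed or repurposed and no default changes semantics. That promise is
*executable* — every command's help text is under golden-file test, so an
incompatible edit fails the suite unless the major version is bumped.
Exit codes are 0 (success), 1 (usage error), 2 (data error). Every
invocation, including failures, prints a citation epilog with the version
to standard error only; machine output (reads, sketches, TSVs) goes to
files, so a downstream consumer in a shell pipeline can never swallow the
epilog by accident.

`run_acceptance_pipeline()` chains quality-filter → count → filter-abund →
normalize-by-median through the CLI, writes each intermediate plus a
retention summary, and compares per-stage retention against tolerance
bands shipped in `inst/extdata/pipeline-bands.tsv`. The bands were
computed from ten seeded 50× development runs and widened generously
against sampling noise; they version with the package, turning
"approximately the expected results" into a concrete, testable contract.

# Known limitations

* k ≤ 32; no minimizers, no multi-k indexing.
* 8-bit counters: abundances above 255 are reported as 255.
* Partitioning is exact only while Bloom occupancy stays low; at high
  occupancy false positives can merge partitions (diagnosed via
  `fp_rate()`).
* Reads are treated independently — no paired-end joint decisions.
* The simulator's error model is substitution-only; indel-induced k-mer
  artifacts are untested.
* Desk-scale distinct-k-mer tracking (`abundance_distribution`,
  partitioning) uses exact sets and scales with distinct k-mers, not with
  sketch memory.
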