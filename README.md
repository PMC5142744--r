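# kmersieve

Fixed-memory pre-filtering of DNA sequencing read sets before mapping or
assembly, for anyone whose data outgrew their downstream tools: CountMin
sketch k-mer counting, a Bloom-filter k-mer graph with read partitioning,
streaming digital normalization, and abundance-based error trimming —
as an R library plus a semantically versioned command line.

## The methods in brief

All structures operate on canonical k-mers (a k-mer identified with its
reverse complement, represented by the lexicographically smaller string;
k ≤ 32, 2-bit packed). A fixed splitmix64-style finalizer maps each k-mer
into N counter/bit tables of distinct prime sizes — no randomized
seeding, so every run is exactly reproducible.

- **Counting (CountMin sketch).** Adding a k-mer increments one 8-bit
  saturating cell per table; a query returns min over tables. Estimates
  are overcount-only: `count(x) ≥ min(true(x), 255)`, with equality unless
  x collided in *every* table (probability ≈ ∏ occupancyᵢ, reported by
  `fp_rate()`).
- **Digital normalization.** One streaming pass with cutoff C: a read is
  kept iff the *median* count of its k-mers — queried before any update —
  is `< C`; only kept reads update the sketch. Keeps roughly C-fold
  coverage per locus, discards the redundant rest, and is idempotent on
  its own output.
- **Node graph / partitioning.** A Bloom set of k-mers with implicit
  edges between k-mers overlapping by k−1; no false negatives.
  Breadth-first traversal yields connected components; reads whose k-mers
  share a component share a partition.
- **Trimming.** After counting the full data set, each read is truncated
  just before its first k-mer with count below a cutoff (default 2) —
  k-mers seen once in deep data are overwhelmingly sequencing errors.

A seeded simulator (`simulate_genome()`, `simulate_reads()`) generates the
error-bearing, two-stranded read sets the tests measure everything on.

## Worked example

Ten identical poly-A reads, k = 4, cutoff C = 3 — small enough to trace by
hand. The first read sees median count 0 and is kept; its five AAAA
windows push that k-mer's count to 5, so every later copy sees median
5 ≥ 3 and is dropped:

```r
library(kmersieve)
reads <- sequence_records(paste0("r", 1:10), rep(strrep("A", 8), 10),
                          strrep("I", 8))
res <- normalize_by_median(reads, diginorm_params(cutoff = 3,
                                                  spec = kmer_spec(4),
                                                  table_size = 1e4))
res$report
#> <diginorm_report> seen 10 | kept 1 (10.0%) | discarded 9 | no-kmer 0
```

The same operation at scale — 50× simulated coverage of a 10 kb genome,
normalized down to C = 5 with k = 20:

```r
genome  <- simulate_genome(10000, seed = 1)
reads50 <- simulate_reads(genome, read_length = 100, coverage = 50,
                          error_rate = 0, seed = 2)
res5 <- normalize_by_median(reads50, diginorm_params(5, kmer_spec(20),
                                                     table_size = 4e6))
res5$report
#> <diginorm_report> seen 5000 | kept 658 (13.2%) | discarded 4342 | no-kmer 0
estimate_retained_coverage(res5$kept, nchar(genome))
#> [1] 6.58
```

87% of the reads are discarded while the surviving set still covers the
genome ~6.6-fold — above the cutoff because each kept read was accepted
while its locus was *below* C. The backing sketch reports its geometry
and collision diagnostics:

```r
res5$sketch
#> <countmin_sketch> k = 20 (canonical), 4 tables
#>   table sizes: 3999971, 3999949, 3999929, 3999923
#>   k-mers consumed: 53298; skipped windows: 0; fp rate: 3.85e-11
```

## Command line

The same operations as shell commands (`exec/kmersieve`), with a frozen
flag surface under semantic versioning — help text is golden-file tested,
exit codes are 0/1/2 (success/usage/data error), and every invocation
prints a citation epilog to stderr only (see `CITATION`):

```sh
kmersieve simulate --length 10000 --coverage 50 --read-length 100 \
          --error-rate 0.002 --seed 1 -o reads.fq
kmersieve normalize-by-median -C 5 -k 20 -o kept.fq reads.fq
kmersieve count -k 20 -o counts.mkm reads.fq
kmersieve filter-abund -C 2 counts.mkm reads.fq -o trimmed.fq
kmersieve partition -k 20 reads.fq -o partitions.tsv
```

`run_acceptance_pipeline()` chains quality filter → count → trim →
normalize, writes each intermediate plus a retention summary, and checks
per-stage retention against the tolerance bands shipped in
`inst/extdata/pipeline-bands.tsv`.

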