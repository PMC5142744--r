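Citing kmersieve
================

If you use kmersieve in published work, please cite the software release
you used. Every command-line invocation prints its version to standard
error; the same string is available in R as packageVersion("kmersieve").

  kmersieve developers (2026). kmersieve: K-mer Counting Sketches and
  Streaming Read Pre-Filtering. R package version 1.0.0.

Please also acknowledge the algorithmic ideas the package implements when
your analysis depends on them: CountMin-sketch abundance counting,
Bloom-filter k-mer graphs, and digital normalization each originate in
their own method literature.
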