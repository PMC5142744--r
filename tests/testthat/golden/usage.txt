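usage: kmersieve [--version] [--help] <command> [args]

commands:
  count                count k-mers from reads into a sketch file
  abund-dist           histogram of k-mer abundances from a sketch
  normalize-by-median  streaming digital normalization of reads
  filter-abund         trim reads at low-abundance k-mers
  quality-filter       drop reads by mean quality and length
  partition            group reads by shared k-mer connectivity
  simulate             generate seeded synthetic reads

run 'kmersieve <command> --help' for command usage
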