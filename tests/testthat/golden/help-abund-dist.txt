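usage: kmersieve abund-dist SKETCH INPUT OUT.tsv

histogram of distinct-k-mer abundances from a sketch

  SKETCH   sketch file written by 'count'
  INPUT    FASTA/FASTQ file the sketch was built from
  OUT.tsv  output: abundance<TAB>n_kmers
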