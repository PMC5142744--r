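usage: kmersieve count -k INT [-N INT] [-x INT] -o SKETCH INPUT...

count k-mers from reads into a sketch file

  -k INT     k-mer length (1..32)
  -N INT     number of sketch tables [4]
  -x INT     approximate table size [1000000]
  -o SKETCH  output sketch file (required)
  INPUT...   FASTA/FASTQ file(s), optionally gzipped
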