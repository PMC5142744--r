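usage: kmersieve partition [-k INT] [-N INT] [-x INT] INPUT -o OUT.tsv

group reads into partitions of shared k-mer connectivity

  -k INT   k-mer length (1..32) [20]
  -N INT   number of graph tables [4]
  -x INT   approximate table size [1000000]
  INPUT    FASTA/FASTQ file, optionally gzipped
  -o OUT   output TSV: read_id<TAB>partition_id
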