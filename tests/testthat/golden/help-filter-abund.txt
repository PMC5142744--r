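usage: kmersieve filter-abund [-C INT] [--min-length INT] SKETCH INPUT -o OUT

trim each read at its first k-mer with abundance below the cutoff;
drop survivors shorter than the minimum length

  -C INT            abundance cutoff [2]
  --min-length INT  minimum surviving read length [k]
  SKETCH            sketch file holding counts of the full data set
  INPUT             FASTA/FASTQ file, optionally gzipped
  -o OUT            output reads (format follows the input)
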