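usage: kmersieve quality-filter [--min-mean-q INT] [--min-len INT] INPUT -o OUT

drop reads whose mean Phred+33 quality or length is too low;
sequences are never modified

  --min-mean-q INT  minimum mean Phred quality [0]
  --min-len INT     minimum read length [1]
  INPUT             FASTQ file (FASTA allowed only without --min-mean-q)
  -o OUT            output reads (format follows the input)
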