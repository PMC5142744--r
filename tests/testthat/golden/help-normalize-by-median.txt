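usage: kmersieve normalize-by-median [-C INT] [-k INT] [-N INT] [-x INT]
                                     [--savetable F | --loadtable F]
                                     -o OUT INPUT

streaming digital normalization: keep a read only while its median
k-mer abundance so far is below the coverage cutoff

  -C INT         coverage cutoff [20]
  -k INT         k-mer length (1..32) [20]
  -N INT         number of sketch tables [4]
  -x INT         approximate table size [1000000]
  --savetable F  write the backing sketch to F after the pass
  --loadtable F  start from the sketch in F instead of a fresh one
  -o OUT         output reads (format follows the input)
  INPUT          FASTA/FASTQ file, optionally gzipped
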