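usage: kmersieve simulate --length INT --coverage FLOAT --read-length INT
                          [--error-rate FLOAT] [--seed INT] -o OUT.fq

generate a seeded random genome and error-bearing shotgun reads

  --length INT       genome length in bases
  --coverage FLOAT   target fold-coverage
  --read-length INT  read length in bases
  --error-rate FLOAT per-base substitution probability [0]
  --seed INT         random seed [1]
  -o OUT.fq          output FASTQ (constant Q40 qualities)
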