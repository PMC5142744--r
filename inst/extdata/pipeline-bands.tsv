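stage	min_retention	max_retention
quality-filter	0.95	1.00
filter-abund	0.88	1.00
normalize-by-median	0.40	0.72
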