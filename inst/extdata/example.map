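chrom	bp	cM
1	1	0.000000
1	2000000	2.150000
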