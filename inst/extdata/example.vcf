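##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	100000	rs1	A	C	.	PASS	.	GT	0|1	1|1	0|0
1	350000	rs2	G	T	.	PASS	.	GT	0|0	0|1	1|0
1	720000	rs3	T	A	.	PASS	.	GT	1|0	0|0	0|1
1	1150000	rs4	C	G	.	PASS	.	GT	0|1	0|1	1|1
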