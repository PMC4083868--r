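##fileformat=VCFv4.2
##source=haplopaint synthetic example (hand-written miniature cohort)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	HG001	HG002	HG003
22	51063477	rs743616	C	G	.	PASS	.	GT	0|1	0|0	1|1
22	51063900	rs1001	A	T	.	PASS	.	GT	0|0	0|1	0|0
22	51064250	rs1002	G	A	.	PASS	.	GT	1|0	.|.	0|0
22	51064800	rs1003	T	C	.	PASS	.	GT	0|0	0|0	0|1
22	51065333	rs1004	C	T	.	PASS	.	GT	0	1	0|0
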