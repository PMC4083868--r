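Subject	Population	SuperPopulation	Age
ID	CATEGORICAL	CATEGORICAL	NUMERICAL
HG001	CEU	EUR	41
HG002	YRI	AFR	35
HG003	CEU	EUR	29
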