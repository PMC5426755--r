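##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SIRE	DAM	PUP1	PUP2	PUP3	PUP4	PUP5	PUP6	PUP7	PUP8
chr20	40532043	.	C	T	.	.	.	GT	0/1	0/1	1/1	1/1	0/1	0/1	0/1	0/1	0/1	0/1
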