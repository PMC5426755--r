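LITTER1	SIRE	0	0	1	1
LITTER1	DAM	0	0	2	1
LITTER1	PUP1	SIRE	DAM	1	2
LITTER1	PUP2	SIRE	DAM	2	2
LITTER1	PUP3	SIRE	DAM	1	1
LITTER1	PUP4	SIRE	DAM	2	1
LITTER1	PUP5	SIRE	DAM	1	1
LITTER1	PUP6	SIRE	DAM	2	1
LITTER1	PUP7	SIRE	DAM	1	1
LITTER1	PUP8	SIRE	DAM	2	1
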