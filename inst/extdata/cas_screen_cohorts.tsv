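label	n_total	n_het	n_hom_alt
Central Asian Shepherd Dog	47	13	2
Caucasian Shepherd Dog	39	0	0
South Russian Ovcharka	3	0	0
Kuvasz	6	0	0
Slovakian Chuvach	19	0	0
Tibetan Mastiff	76	0	0
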