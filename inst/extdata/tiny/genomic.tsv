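patient_id	mutational_burden	scna_rate	lym_abundance
P001	51	30	0.148409893992933
P002	62	48	0.225085910652921
P003	49	18	0.16914749661705
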