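individual	parent1	parent2	cross_type	dna_fraction
A_P002_D02	A004	A002	F1DH	NA
A_P001_D02	A003	A001	F1DH	NA
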