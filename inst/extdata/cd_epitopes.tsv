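name	hla	sequence	deamidation_mask
DQ2.5-glia-g1	DQ2.5	PQQSFPQQQ
DQ2.5-glia-g2	DQ2.5	IQPQQPAQL
DQ2.5-glia-g3	DQ2.5	QQPQQPYPQ
DQ2.5-glia-g4b	DQ2.5	PQPQQQFPQ
DQ2.5-glia-g4c	DQ2.5	QQPQQPFPQ
DQ2.5-glia-g5	DQ2.5	QQPFPQQPQ
DQ2.5-glia-o1	DQ2.5	PFPQPQQPF
DQ8-glia-g1a	DQ8	QQPQQPFPQ
DQ8-glia-g1b	DQ8	QQPQQPYPQ
DQ8.5-glia-g1	DQ8.5	PQQSFPQQQ
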