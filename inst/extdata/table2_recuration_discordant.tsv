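bucket	P_LP	B_LB	VUS
DISEASE	1	31	20
POLYMORPHISM	6	4	8
UNCLASSIFIED	4	16	10
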