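bucket	P_LP	B_LB	VUS
DISEASE	1328	111	94
POLYMORPHISM	46	2328	128
UNCLASSIFIED	55	81	115
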