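rule	class	pvs	ps	pm	pp	ba	bs	bp	note
P1a	PATHOGENIC	1	1	0	0	0	0	0	1 very strong + >=1 strong
P1b	PATHOGENIC	1	0	2	0	0	0	0	1 very strong + >=2 moderate
P1c	PATHOGENIC	1	0	1	1	0	0	0	1 very strong + 1 moderate + 1 supporting
P1d	PATHOGENIC	1	0	0	2	0	0	0	1 very strong + >=2 supporting
P2	PATHOGENIC	0	2	0	0	0	0	0	>=2 strong
P3a	PATHOGENIC	0	1	3	0	0	0	0	1 strong + >=3 moderate
P3b	PATHOGENIC	0	1	2	2	0	0	0	1 strong + 2 moderate + >=2 supporting
P3c	PATHOGENIC	0	1	1	4	0	0	0	1 strong + 1 moderate + >=4 supporting
LP1	LIKELY_PATHOGENIC	1	0	1	0	0	0	0	1 very strong + 1 moderate
LP2	LIKELY_PATHOGENIC	0	1	1	0	0	0	0	1 strong + 1-2 moderate
LP3	LIKELY_PATHOGENIC	0	1	0	2	0	0	0	1 strong + >=2 supporting
LP4	LIKELY_PATHOGENIC	0	0	3	0	0	0	0	>=3 moderate
LP5	LIKELY_PATHOGENIC	0	0	2	2	0	0	0	2 moderate + >=2 supporting
LP6	LIKELY_PATHOGENIC	0	0	1	4	0	0	0	1 moderate + >=4 supporting
B1	BENIGN	0	0	0	0	1	0	0	>=1 stand-alone
B2	BENIGN	0	0	0	0	0	2	0	>=2 strong benign
LB1	LIKELY_BENIGN	0	0	0	0	0	1	1	1 strong benign + >=1 supporting benign
LB2	LIKELY_BENIGN	0	0	0	0	0	0	2	>=2 supporting benign
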