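gene	accession	variant	dbsnp	hgvs_c	condition	submitter	classification	criteria_provided	expert_panel	practice_guideline
GLI3	P10071	p.Ile808Met	rs35364414	NM_000168.5:c.2424A>G	Greig cephalopolysyndactyly syndrome	LAB_A	Benign	yes	no	no
GLI3	P10071	p.Ile808Met	rs35364414	NM_000168.5:c.2424A>G	Greig cephalopolysyndactyly syndrome	LAB_B	Likely benign	yes	no	no
ATP7B	P35670	p.Met645Arg	rs121907990	NM_000053.3:c.1934T>G	Wilson disease	LAB_A	Pathogenic	yes	no	no
ATP7B	P35670	p.Met645Arg	rs121907990	NM_000053.3:c.1934T>G	Wilson disease	LAB_C	Pathogenic	yes	no	no
GENEA	P90001	p.Ala100Val	rs900000001		Synthetic disorder A	LAB_A	Benign	yes	no	no
GENEA	P90001	p.Ala100Val	rs900000001		Synthetic disorder A	LAB_B	Benign	yes	no	no
GENEB	P90002	p.Gly50Asp	rs900000002		Synthetic disorder B	LAB_A	Pathogenic	yes	no	no
GENEB	P90002	p.Gly50Asp	rs900000002		Synthetic disorder B	LAB_B	Uncertain significance	yes	no	no
GENEC	P90003	p.Arg7Cys	rs900000003		Synthetic disorder C	LAB_A	Uncertain significance	yes	no	no
GENEC	P90003	p.Arg7Cys	rs900000003		Synthetic disorder C	LAB_B	VUS	yes	no	no
GENED	P90004	p.Leu20Pro	rs900000004		Multifactorial disorder D	LAB_A	Pathogenic	yes	no	no
GENED	P90004	p.Leu20Pro	rs900000004		Multifactorial disorder D	LAB_B	Likely pathogenic	yes	no	no
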