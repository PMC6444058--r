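gene	accession	variant	category	dbsnp	disease	omim	inheritance	prevalence	penetrance	carrier_frequency	mendelian	hgvs_c
GLI3	P10071	p.Ile808Met	Disease	rs35364414	Greig cephalopolysyndactyly syndrome	175700	AD	1e-06	0.9		yes	NM_000168.5:c.2424A>G
ATP7B	P35670	p.Met645Arg	Disease	rs121907990	Wilson disease	277900	AR	3.3e-05	0.9	0.011	yes	NM_000053.3:c.1934T>G
GENEA	P90001	p.Ala100Val	Polymorphism	rs900000001	Synthetic disorder A		AD			 	yes	
GENEB	P90002	p.Gly50Asp	Disease	rs900000002	Synthetic disorder B		AR				yes	
GENEC	P90003	p.Arg7Cys	Unclassified	rs900000003	Synthetic disorder C		AD				yes	
GENED	P90004	p.Leu20Pro	Disease	rs900000004	Multifactorial disorder D		AD				no	
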