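code	strength	justification	source
BS1		allele frequency close to 0.2% in ExAC and gnomAD is greater than expected for GCPS (prevalence about 1 in 1000000)	ExAC r0.3; gnomAD r2.0
BS2	SUPPORTING	observed heterozygous in healthy adults; applied as supporting only because GCPS penetrance is not 100%	ExAC r0.3
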