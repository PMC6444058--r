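code	strength	justification	source
PM2		overall frequency 0.05% in ExAC is well below the carrier frequency of 1.1% and no homozygote is reported	ExAC r0.3; gnomAD r2.0
PM3		repeatedly detected in trans with a pathogenic variant in Wilson disease patients	literature
BS3		copper transport activity comparable to wild type in well-established functional assays	literature
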