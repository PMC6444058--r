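sample	outcome	count
discordant	solved	78
discordant	modified_without_agreement	7
discordant	retained	15
concordant	confirmed	96
concordant	modified	4
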