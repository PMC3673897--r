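class	cds_sites	total_sites
conserved	182	192
less_conserved	40	47
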