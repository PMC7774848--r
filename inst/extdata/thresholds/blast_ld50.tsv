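species	mass_g	ld50_Pa
mouse	20.7	184000
rat	168	220798
guinea_pig	590	250000
rabbit	2500	290000
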