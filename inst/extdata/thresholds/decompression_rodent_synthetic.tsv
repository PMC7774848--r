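species	mass_g	delta_p_Pa	duration_s	hemorrhage_pct	mortality_pct
rat	168	-63959.7543685231	0.757200800049328	50	18
rat	168	-51984.4226462301	0.304974646394234	21	0
rat	168	-84197.172074113	0.616325497155404	100	85
rat	168	-66640.6557096634	0.326040502997418	55	27
rat	168	-65283.101093024	1.60780919571284	51	22
rat	168	-51835.4949641507	1.81791282835084	25	0
rat	168	-51029.3353705201	1.49576803434994	16	0
rat	168	-82257.78315356	0.854983004817041	100	79
rat	168	-70351.2231307104	1.09865308881304	70	39
rat	168	-70218.7615463044	1.31320830078688	70	39
rat	168	-58600	0.1	40	10
rabbit	2500	-72000	0.5	60	50
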