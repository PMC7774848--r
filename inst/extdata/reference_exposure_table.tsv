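u_inf_mps	p_min_close_Pa	p_min_far_Pa	p_vortex_min_Pa	p_max_close_Pa	p_max_far_Pa
5	-2477	-1837	-944	1086	873
7.5	-4057	-2916	-2545	1462	1198
10	-7077	-5011	-4556	2304	1947
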