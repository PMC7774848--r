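alpha_deg	cl	cd
-180	0	0.35
-170	0	0.35
-160	0	0.35
-150	0	0.35
-140	0	0.35
-130	0	0.35
-120	0	0.35
-110	0	0.35
-100	0	0.35
-90	0	0.35
-80	0	0.35
-70	0	0.35
-60	0	0.35
-50	0	0.35
-40	0	0.35
-30	0	0.35
-20	0	0.35
-10	0	0.35
0	0	0.35
10	0	0.35
20	0	0.35
30	0	0.35
40	0	0.35
50	0	0.35
60	0	0.35
70	0	0.35
80	0	0.35
90	0	0.35
100	0	0.35
110	0	0.35
120	0	0.35
130	0	0.35
140	0	0.35
150	0	0.35
160	0	0.35
170	0	0.35
180	0	0.35
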