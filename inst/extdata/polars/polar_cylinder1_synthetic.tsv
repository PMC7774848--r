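alpha_deg	cl	cd
-180	0	0.5
-170	0	0.5
-160	0	0.5
-150	0	0.5
-140	0	0.5
-130	0	0.5
-120	0	0.5
-110	0	0.5
-100	0	0.5
-90	0	0.5
-80	0	0.5
-70	0	0.5
-60	0	0.5
-50	0	0.5
-40	0	0.5
-30	0	0.5
-20	0	0.5
-10	0	0.5
0	0	0.5
10	0	0.5
20	0	0.5
30	0	0.5
40	0	0.5
50	0	0.5
60	0	0.5
70	0	0.5
80	0	0.5
90	0	0.5
100	0	0.5
110	0	0.5
120	0	0.5
130	0	0.5
140	0	0.5
150	0	0.5
160	0	0.5
170	0	0.5
180	0	0.5
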