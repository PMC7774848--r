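alpha_deg	cl	cd
-180	2.44929359829471e-16	0.035
-170	0.342020143325669	0.0603073792140916
-160	0.64278760968654	0.233955556881022
-150	0.866025403784439	0.5
-140	0.984807753012208	0.82635182233307
-130	0.984807753012208	1.17364817766693
-120	0.866025403784438	1.5
-110	0.642787609686539	1.76604444311898
-100	0.342020143325669	1.93969262078591
-90	-1.22466932556692e-16	2
-80	-0.342020143325669	1.93969262078591
-70	-0.642787609686541	1.76604444311898
-60	-0.866025403785208	1.49999999999976
-50	-0.984807753509749	1.17364817752094
-40	-0.984808057888091	0.826351742491692
-30	-0.866197892252595	0.499963094472083
-29	-0.848371130130521	0.470013480054753
-28	-0.829641601624534	0.440684928967722
-27	-0.81014446477573	0.411993630261834
-26	-0.790110992452248	0.383939928089229
-25	-0.769947088907834	0.356497219932477
-24	-0.750373550899189	0.329593452631523
-23	-0.732669707494641	0.303081565966169
-22	-0.719073975810718	0.276696164897839
-21	-0.713367824394361	0.250001946822297
-20	-0.721485696986069	0.222369644433792
-19	-0.75138219760762	0.19309256691471
-18	-0.810170053665948	0.161867054525321
-17	-0.896306548495802	0.129746642926553
-16	-0.990725318915606	0.099796781907405
-15	-1.06144886652686	0.0757987290943072
-14	-1.08517300642861	0.0595061256775784
-13	-1.06063915510478	0.0498186579341364
-12	-1.00062374081404	0.0444329988254322
-11	-0.91917969310595	0.04140640703865
-10	-0.826171072179854	0.0395636711055902
-9	-0.727282871095983	0.0383080723184255
-8	-0.625481748373038	0.0373666812471082
-7	-0.522239618320596	0.0366367056868976
-6	-0.418271131929562	0.0360497126760771
-5	-0.313924082306603	0.035591248982883
-4	-0.209373430627936	0.0352629943471642
-3	-0.104714406598262	0.0350657793526114
-2	-6.16780951190034e-06	0.035
-1	0.104690396741444	0.0350657793526114
0	0.209326758910371	0.0352629943471642
1	0.313833484227302	0.035591248982883
2	0.418095534401832	0.0360497126760771
3	0.521899896138243	0.0366367056868976
4	0.62482607135052	0.0373487196198747
5	0.726021780702941	0.0381781753911025
6	0.823758969395356	0.0391084872694553
7	0.914609342727758	0.0401038225098611
8	0.992106329047472	0.041332914469414
9	1.04521976216132	0.0435888187985216
10	1.0585855535094	0.0476686289686555
11	1.01890995194445	0.0550511141702461
12	0.929134008336903	0.0670481011643175
13	0.816472803282915	0.0836546086374767
14	0.716537608689845	0.103359009315418
15	0.649507908106169	0.12437749099871
16	0.615950314157765	0.145693700599702
17	0.607216947193324	0.167067792224048
18	0.61412309998684	0.188631923702291
19	0.629957245542434	0.210598849824614
20	0.650498526730652	0.233145262908382
21	0.673272883544686	0.256388149717322
22	0.696877261701701	0.280393379913457
23	0.720525826838708	0.305190296536989
24	0.743777658690826	0.330784093702618
25	0.766381598335099	0.357164570823638
26	0.788190140065496	0.384311845838077
27	0.809112322668572	0.412199927753598
28	0.829088174558353	0.440798896413195
29	0.848074928661323	0.47007621477364
30	0.866039618272055	0.499997515639349
40	0.984807776704596	0.826351816901441
50	0.984807753049458	1.17364817765693
60	0.866025403784495	1.49999999999998
70	0.64278760968654	1.76604444311898
80	0.342020143325669	1.93969262078591
90	1.22464836436073e-16	2
100	-0.342020143325669	1.93969262078591
110	-0.642787609686539	1.76604444311898
120	-0.866025403784438	1.5
130	-0.984807753012208	1.17364817766693
140	-0.984807753012208	0.82635182233307
150	-0.866025403784439	0.5
160	-0.64278760968654	0.233955556881022
170	-0.342020143325669	0.0603073792140916
180	-2.44929359829471e-16	0.035
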