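alpha_deg	cl	cd
-180	2.44929359829471e-16	0.02
-170	0.342020143325669	0.0603073792140916
-160	0.64278760968654	0.233955556881022
-150	0.866025403784439	0.5
-140	0.984807753012208	0.82635182233307
-130	0.984807753012208	1.17364817766693
-120	0.866025403784438	1.5
-110	0.642787609686539	1.76604444311898
-100	0.342020143325669	1.93969262078591
-90	-1.22466651595175e-16	2
-80	-0.342020143325669	1.93969262078591
-70	-0.64278760968654	1.76604444311898
-60	-0.866025403785114	1.49999999999979
-50	-0.984807753449396	1.17364817753738
-40	-0.984808021454678	0.826351751052823
-30	-0.866177792422249	0.499966588649865
-29	-0.848333622877735	0.470019705604805
-28	-0.829571745060928	0.440695946593616
-27	-0.810014646075501	0.412012974333943
-26	-0.789870388124142	0.38397356551088
-25	-0.769502690250135	0.356555007389447
-24	-0.749556657201336	0.329691152926376
-23	-0.731178855739243	0.303243074891238
-22	-0.716384635999919	0.276954206472475
-21	-0.708612206030328	0.250391493881407
-20	-0.713366390532179	0.222898635550001
-19	-0.738354617746865	0.193657976736245
-18	-0.791385978872538	0.162083792013952
-17	-0.873540850327627	0.128763643818623
-16	-0.969530720324509	0.0964341967993659
-15	-1.04839271033755	0.0692396445556153
-14	-1.08312109230003	0.049878543541042
-13	-1.06803585031817	0.0379333881068956
-12	-1.01427368699663	0.0311633317642276
-11	-0.936387690481242	0.0273737239943559
-10	-0.8452421650534	0.025130277601209
-9	-0.747290242848887	0.0236646347819018
-8	-0.645953262679895	0.0226083757286612
-7	-0.542942899814302	0.0217966778250421
-6	-0.43909301031283	0.0211595954810327
-5	-0.334808709792827	0.0206725626049595
-4	-0.23029192777355	0.0203181807976318
-3	-0.125650362555089	0.0200947157094722
-2	-0.0209488399854624	0.0200026316179203
-1	0.0837551968480383	0.0200421012295939
0	0.188409239787905	0.0202130507806066
1	0.292951056833251	0.0205151462252638
2	0.397278616377167	0.0209476661658096
3	0.501206531278609	0.0215091541313283
4	0.604372180673128	0.022196591799273
5	0.706042340548119	0.0230034939421102
6	0.804726870151975	0.0239449013203143
7	0.897448858154094	0.025196155508793
8	0.978514963646236	0.0269732299900577
9	1.03795154598974	0.029846071906853
10	1.06109146060037	0.0348952338818894
11	1.03331446163435	0.0436895224717532
12	0.953066996644691	0.0575694636479736
13	0.842978642270706	0.0763921973744027
14	0.73895730594492	0.098293906508366
15	0.665292565177676	0.121126881806697
16	0.625852488207025	0.143730989887998
17	0.613022322541322	0.165928468493962
18	0.617398988299843	0.187986082458559
19	0.63176658987648	0.210237843541478
20	0.651485694415759	0.232945166510982
21	0.673807541340361	0.256277834594874
22	0.69716548065478	0.280332786829514
23	0.720680692193778	0.305157107829456
24	0.743860666719762	0.330765957486748
25	0.76642600257612	0.357154680530909
26	0.788213853513432	0.384306462558445
27	0.809124967594707	0.412197002895718
28	0.829094908216188	0.440797310005023
29	0.848078510011771	0.470075355753213
30	0.866041520851232	0.499997051238216
40	0.984807779944581	0.826351815986008
50	0.984807753054624	1.17364817765533
60	0.866025403784503	1.49999999999998
70	0.64278760968654	1.76604444311898
80	0.342020143325669	1.93969262078591
90	1.22464858781549e-16	2
100	-0.342020143325669	1.93969262078591
110	-0.642787609686539	1.76604444311898
120	-0.866025403784438	1.5
130	-0.984807753012208	1.17364817766693
140	-0.984807753012208	0.82635182233307
150	-0.866025403784439	0.5
160	-0.64278760968654	0.233955556881022
170	-0.342020143325669	0.0603073792140916
180	-2.44929359829471e-16	0.02
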