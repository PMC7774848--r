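alpha_deg	cl	cd
-180	2.44929359829471e-16	0.01
-170	0.342020143325669	0.0603073792140916
-160	0.64278760968654	0.233955556881022
-150	0.866025403784439	0.5
-140	0.984807753012208	0.82635182233307
-130	0.984807753012208	1.17364817766693
-120	0.866025403784438	1.5
-110	0.642787609686539	1.76604444311898
-100	0.342020143325669	1.93969262078591
-90	-1.22468517532676e-16	2
-80	-0.342020143325669	1.93969262078591
-70	-0.642787609686541	1.76604444311898
-60	-0.866025403785737	1.49999999999958
-50	-0.984807753846529	1.17364817741124
-40	-0.98480825997266	0.826351680880053
-30	-0.866308221139278	0.499932953591404
-29	-0.848576689039931	0.469958058948414
-28	-0.830023782406602	0.440583267457601
-27	-0.810853258692598	0.411807649881152
-26	-0.791421451541149	0.38360077696319
-25	-0.772359924357366	0.35588123589373
-24	-0.754789570666488	0.328480841088997
-23	-0.740676679998194	0.301088485753196
-22	-0.733367099407455	0.273173048491438
-21	-0.738199296629551	0.243912309722894
-20	-0.762608122629457	0.212239088116826
-19	-0.81403680966865	0.177277919368598
-18	-0.893268841370117	0.139477076671584
-17	-0.985141884871412	0.101905045977292
-16	-1.0594550524256	0.0695839680413583
-15	-1.0901876689136	0.0461103630857395
-14	-1.07220106335862	0.0313949490368134
-13	-1.01660053688	0.0229839014535691
-12	-0.937646087099667	0.0182995388956485
-11	-0.84591015501256	0.0155916850201151
-10	-0.747641085361293	0.0138917453157003
-9	-0.64613639335418	0.0127192273835007
-8	-0.54303812236677	0.0118504356246047
-7	-0.439142394460313	0.0111855171009324
-6	-0.334834271361586	0.0106814048365622
-5	-0.230305137349595	0.0103201702749
-4	-0.125657179204922	0.0100947157094722
-3	-0.0209523529715346	0.0100026316179203
-2	0.0837499435405474	0.0100421012295939
-1	0.18839899672375	0.0102130507806066
0	0.292931111616505	0.0105151462252638
1	0.397239836734212	0.0109476661658096
2	0.501131262372096	0.0115091541313283
3	0.604226412839108	0.012196591799273
4	0.705760935281488	0.0130034939421102
5	0.80418631280451	0.0139975923335614
6	0.896419175669704	0.0152611914960577
7	0.976582252674226	0.0170286034048936
8	1.03441667690664	0.0198243435955698
9	1.05490502716135	0.0246395719510136
10	1.02321183053691	0.0329117409229407
11	0.938071389616638	0.0458713657282777
12	0.823040672908483	0.0633975718019161
13	0.715055865474239	0.0838007621439684
14	0.638852737093487	0.105131766897534
15	0.598133910828989	0.12634044655672
16	0.58489520654341	0.147270848562203
17	0.589392754316303	0.168170916208599
18	0.604186707175545	0.189348605461967
19	0.624508382135968	0.211044506779297
20	0.647538945176493	0.233414649335046
21	0.671674783866506	0.256547807127187
22	0.696017675372475	0.280486630719814
23	0.720064762787405	0.305244143052288
24	0.743530890644083	0.330814899492898
25	0.76624976226433	0.357182058437113
26	0.788119816476228	0.38432170714991
27	0.809074863243909	0.412205456353096
28	0.829068246360459	0.440801980063589
29	0.848064339433215	0.470077926848546
30	0.866033997638168	0.499998462279752
40	0.98480776719504	0.826351819045723
50	0.984807753034359	1.17364817766094
60	0.866025403784472	1.49999999999999
70	0.642787609686539	1.76604444311898
80	0.342020143325669	1.93969262078591
90	1.22464771683666e-16	2
100	-0.342020143325669	1.93969262078591
110	-0.642787609686539	1.76604444311898
120	-0.866025403784438	1.5
130	-0.984807753012208	1.17364817766693
140	-0.984807753012208	0.82635182233307
150	-0.866025403784439	0.5
160	-0.64278760968654	0.233955556881022
170	-0.342020143325669	0.0603073792140916
180	-2.44929359829471e-16	0.01
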