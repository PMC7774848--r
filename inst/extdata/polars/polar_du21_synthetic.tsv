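alpha_deg	cl	cd
-180	2.44929359829471e-16	0.009
-170	0.342020143325669	0.0603073792140916
-160	0.64278760968654	0.233955556881022
-150	0.866025403784439	0.5
-140	0.984807753012208	0.82635182233307
-130	0.984807753012208	1.17364817766693
-120	0.866025403784438	1.5
-110	0.642787609686539	1.76604444311898
-100	0.342020143325669	1.93969262078591
-90	-1.22469688495708e-16	2
-80	-0.342020143325669	1.93969262078591
-70	-0.642787609686542	1.76604444311898
-60	-0.866025403786124	1.49999999999946
-50	-0.984807754092396	1.1736481773323
-40	-0.984808406523976	0.8263516370378
-30	-0.866387291071678	0.499912031096446
-29	-0.84872374234011	0.469919744174209
-28	-0.830296626709088	0.440513307356172
-27	-0.811358051376238	0.411680340096619
-26	-0.792351935465301	0.383370066310413
-25	-0.774066304018587	0.355465426825917
-24	-0.757894718472725	0.32773728989804
-23	-0.746256798378758	0.2997749787166
-22	-0.743182186600977	0.270899025221538
-21	-0.754824254642634	0.24010909088818
-20	-0.788956931820055	0.206244396766055
-19	-0.851307876829285	0.168708992959237
-18	-0.937148409712332	0.128907964585155
-17	-1.02422076683956	0.0911445180912142
-16	-1.08146535299194	0.0606339077418816
-15	-1.09070475203147	0.0397660861823404
-14	-1.05494351827047	0.0272236248023501
-13	-0.987843544104609	0.0201847024608489
-12	-0.902438738683588	0.0162473417739709
-11	-0.807356727574581	0.0139224706115759
-10	-0.707416688698006	0.0124222940756274
-9	-0.605086801408505	0.0113646546075657
-8	-0.501576920762025	0.0105735269112286
-7	-0.397470156612594	0.00997070041636171
-6	-0.293049934067522	0.00952249142829807
-5	-0.18846020583591	0.00921486821607568
-4	-0.0837814313915603	0.00904221153921596
-3	0.0209312321187659	0.00900263161792026
-2	0.125616070397167	0.00909471570947224
-1	0.230225229583561	0.0093181807976318
0	0.334679163245344	0.00967256260495948
1	0.438841789840466	0.0101569057248508
2	0.542456653124793	0.0107692700510447
3	0.645014508151016	0.0115055717917101
4	0.745484704281298	0.0123647297045426
5	0.84179070648235	0.0134309511719885
6	0.929858964134449	0.0148085149900582
7	1.00215087389931	0.0167982084103514
8	1.04624125733431	0.0200404344737207
9	1.04597983633853	0.0256592431245034
10	0.989981273347298	0.035069081711127
11	0.886704952039495	0.0490984844049849
12	0.768349921166967	0.0670450789465462
13	0.669979516516398	0.0870734821657424
14	0.607646065234419	0.107609961654212
15	0.57876396289949	0.128018435125378
16	0.573615583619961	0.14833120970202
17	0.583056336125438	0.168813536871776
18	0.600698131052013	0.189728123097294
19	0.622609695162249	0.211264913020183
20	0.646512663727508	0.23354116980559
21	0.671122499323683	0.256619807283416
22	0.695721378618993	0.280527323745256
23	0.719906169335165	0.305267010440591
24	0.743446162208188	0.330827686256431
25	0.766204568578726	0.357189177077676
26	0.788095744553143	0.384325654577098
27	0.809062058053437	0.412207637392091
28	0.829061442611098	0.44080318114198
29	0.848060728377294	0.470078586243906
30	0.86603208305199	0.49999882325791
40	0.984807763982875	0.826351819816969
50	0.984807753029287	1.17364817766234
60	0.866025403784464	1.49999999999999
70	0.642787609686539	1.76604444311898
80	0.342020143325669	1.93969262078591
90	1.22464750177448e-16	2
100	-0.342020143325669	1.93969262078591
110	-0.642787609686539	1.76604444311898
120	-0.866025403784438	1.5
130	-0.984807753012208	1.17364817766693
140	-0.984807753012208	0.82635182233307
150	-0.866025403784439	0.5
160	-0.64278760968654	0.233955556881022
170	-0.342020143325669	0.0603073792140916
180	-2.44929359829471e-16	0.009
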