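alpha_deg	cl	cd
-180	2.44929359829471e-16	0.013
-170	0.342020143325669	0.0603073792140916
-160	0.64278760968654	0.233955556881022
-150	0.866025403784439	0.5
-140	0.984807753012208	0.82635182233307
-130	0.984807753012208	1.17364817766693
-120	0.866025403784438	1.5
-110	0.642787609686539	1.76604444311898
-100	0.342020143325669	1.93969262078591
-90	-1.22467253523408e-16	2
-80	-0.342020143325669	1.93969262078591
-70	-0.642787609686541	1.76604444311898
-60	-0.866025403785316	1.49999999999972
-50	-0.984807753578416	1.1736481774964
-40	-0.984808099247698	0.826351728180968
-30	-0.866220621933928	0.499955545494127
-29	-0.848413520643625	0.469999440789202
-28	-0.829720502869209	0.440658854166249
-27	-0.810290984457586	0.411945273366429
-26	-0.790382312491162	0.383850402585958
-25	-0.770447664414049	0.35633184147066
-24	-0.751292320524068	0.329288900902847
-23	-0.734342754483996	0.302523422964443
-22	-0.722081313371641	0.27568148974861
-21	-0.718654235833205	0.248183003989737
-20	-0.730418895408545	0.219188052482084
-19	-0.765463743352522	0.187755699409502
-18	-0.829884308557936	0.153491077186712
-17	-0.919127789570209	0.117768749626756
-16	-1.01055829214892	0.0844051394382491
-15	-1.07218961757376	0.0578203815410889
-14	-1.0849822027952	0.0398442261713099
-13	-1.0516500164913	0.0291219059789652
-12	-0.986030122249276	0.0231097932586459
-11	-0.90146597919656	0.0197133271015506
-10	-0.806842628365124	0.0176620205276038
-9	-0.707147298146417	0.0162968851853434
-8	-0.604946356077364	0.0153048861006229
-7	-0.501503938863148	0.0145453129026422
-6	-0.397432319034289	0.0139575147789705
-5	-0.293030352318188	0.0135163991041149
-4	-0.188450087339776	0.0132130507806066
-3	-0.0837762100858089	0.0130421012295939
-2	0.020934745104838	0.0130026316179203
-1	0.125622928826713	0.0130947157094722
0	0.230238601781671	0.0133181807976318
1	0.334705199276171	0.0136725626049595
2	0.438892403534387	0.0141569057248508
3	0.542554859632297	0.0147692700510447
4	0.645204578988659	0.0155055717917101
5	0.745851194234886	0.0163802537031817
6	0.842493074573594	0.017485481659565
7	0.931190998387198	0.0189593764373207
8	1.00463078682557	0.0211684823685042
9	1.0507117218394	0.0248714810800013
10	1.05361924738712	0.0313638024317965
11	1.00202978013957	0.0422151110362298
12	0.903839394671329	0.0582384876389824
13	0.790176921452265	0.0784632784096216
14	0.695250165972527	0.100699320360876
15	0.63494157262887	0.123163704315895
16	0.606968129967026	0.14519450511233
17	0.60200294317261	0.166887279314286
18	0.611197598563559	0.188581366852707
19	0.628346812431209	0.210595549215201
20	0.649621695904928	0.233155629986401
21	0.672798637244667	0.256399876542365
22	0.696621862866423	0.28040279861806
23	0.72038870295229	0.305196934096247
24	0.743704207656826	0.3307884561038
25	0.766342328640198	0.357167315607722
26	0.788169179248507	0.384313521869999
27	0.809101150717615	0.412200928978609
28	0.82908222783201	0.440799484552348
29	0.848071767108718	0.47007655567999
30	0.866037939337337	0.499997711103478
40	0.984807773853498	0.826351817434035
50	0.98480775304492	1.173648177658
60	0.866025403784488	1.49999999999999
70	0.64278760968654	1.76604444311898
80	0.342020143325669	1.93969262078591
90	1.22464816880501e-16	2
100	-0.342020143325669	1.93969262078591
110	-0.642787609686539	1.76604444311898
120	-0.866025403784438	1.5
130	-0.984807753012208	1.17364817766693
140	-0.984807753012208	0.82635182233307
150	-0.866025403784439	0.5
160	-0.64278760968654	0.233955556881022
170	-0.342020143325669	0.0603073792140916
180	-2.44929359829471e-16	0.013
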