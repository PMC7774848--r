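alpha_deg	cl	cd
-180	2.44929359829471e-16	0.0075
-170	0.342020143325669	0.0603073792140916
-160	0.64278760968654	0.233955556881022
-150	0.866025403784439	0.5
-140	0.984807753012208	0.82635182233307
-130	0.984807753012208	1.17364817766693
-120	0.866025403784438	1.5
-110	0.642787609686539	1.76604444311898
-100	0.342020143325669	1.93969262078591
-90	-1.22474424293874e-16	2
-80	-0.342020143325669	1.93969262078591
-70	-0.642787609686544	1.76604444311898
-60	-0.866025403787675	1.49999999999894
-50	-0.984807755071213	1.1736481770119
-40	-0.984808984709786	0.826351458940761
-30	-0.866694161727838	0.499826969705841
-29	-0.849292967911719	0.469763988571521
-28	-0.831349558893809	0.440228993650945
-27	-0.813298848321321	0.4111633220959
-26	-0.795912100761278	0.382434509657358
-25	-0.780550899968307	0.353784299453493
-24	-0.769573844074322	0.324748700416065
-23	-0.766896950439736	0.294555040476103
-22	-0.778474345065401	0.262052825730528
-21	-0.811771866575923	0.225876225140987
-20	-0.872154983366146	0.185243434146351
-19	-0.954717684255332	0.141592752908777
-18	-1.03756527241855	0.0996885154339286
-17	-1.09054092818584	0.0654926934637452
-16	-1.09631311191857	0.0419171034653258
-15	-1.05817644809012	0.0276745155074523
-14	-0.989626349821738	0.0196790736090788
-13	-0.903396495174172	0.0152393644981579
-12	-0.807863626395539	0.0126613011030721
-11	-0.707682677915496	0.0110366416266589
-10	-0.605225662653962	0.00991877964134699
-9	-0.501649175727257	0.00909886443388283
-8	-0.39750766627695	0.00848241990468362
-7	-0.293069371050001	0.00802783606591947
-6	-0.188470262237766	0.00771726323523649
-5	-0.083786627142715	0.00754326053089174
-4	0.0209277319989466	0.00750285710813616
-3	0.125609228689694	0.00759471570947224
-2	0.230211873677413	0.0078181807976318
-1	0.334653127214518	0.00817256260495948
0	0.438791114406335	0.0086569057248508
1	0.542358206587096	0.00926927005104474
2	0.644823738623161	0.0100055717917101
3	0.745116411796617	0.0108569488530245
4	0.841084001547702	0.0118497686211126
5	0.92851700887634	0.0131064138963332
6	0.999649281279188	0.0148310015126139
7	1.04172581694353	0.017531417700026
8	1.03825327727661	0.0221442097819218
9	0.977778696411246	0.0299220071843761
10	0.869327118343101	0.0417276850994895
11	0.746181006824282	0.0571698948270596
12	0.644274893975697	0.0748060451355366
13	0.579839151016774	0.0932827827450589
14	0.54998554319016	0.111980310330141
15	0.544602145815156	0.130852763964528
16	0.554244531630505	0.150079267551411
17	0.57233916931198	0.169858720454393
18	0.594850761756633	0.190340745053292
19	0.619445247734465	0.211619161551681
20	0.644808810184376	0.233743997487548
21	0.670208203748961	0.256735046027048
22	0.695231983498939	0.280592384351705
23	0.719644724733308	0.305303543389223
24	0.743306722977168	0.330848102829791
25	0.766130306813902	0.357200538374019
26	0.788056245793351	0.384331952409782
27	0.809041074113417	0.412211116067758
28	0.829050306999712	0.440805096351383
29	0.848054825055099	0.470079637483613
30	0.866028956526805	0.499999398646503
40	0.984807758781303	0.826351821045348
50	0.984807753021119	1.17364817766458
60	0.866025403784452	1.5
70	0.642787609686539	1.76604444311898
80	0.342020143325669	1.93969262078591
90	1.22464715948121e-16	2
100	-0.342020143325669	1.93969262078591
110	-0.642787609686539	1.76604444311898
120	-0.866025403784438	1.5
130	-0.984807753012208	1.17364817766693
140	-0.984807753012208	0.82635182233307
150	-0.866025403784439	0.5
160	-0.64278760968654	0.233955556881022
170	-0.342020143325669	0.0603073792140916
180	-2.44929359829471e-16	0.0075
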