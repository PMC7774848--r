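17%-thick cambered 4-digit section (synthetic 64-series stand-in)
1.00000000 -0.00000000
0.99962522 0.00013004
0.99850133 0.00051954
0.99662975 0.00116664
0.99401280 0.00206823
0.99065378 0.00322003
0.98655691 0.00461658
0.98172736 0.00625130
0.97617128 0.00811654
0.96989577 0.01020367
0.96290890 0.01250308
0.95521973 0.01500432
0.94683830 0.01769614
0.93777563 0.02056657
0.92804376 0.02360303
0.91765571 0.02679235
0.90662549 0.03012090
0.89496810 0.03357466
0.88269955 0.03713926
0.86983681 0.04080007
0.85639782 0.04454228
0.84240149 0.04835094
0.82786766 0.05221101
0.81281709 0.05610741
0.79727144 0.06002506
0.78125327 0.06394894
0.76478596 0.06786409
0.74789373 0.07175566
0.73060162 0.07560891
0.71293539 0.07940925
0.69492156 0.08314228
0.67658735 0.08679374
0.65796064 0.09034962
0.63906993 0.09379610
0.61994432 0.09711962
0.60061346 0.10030688
0.58110750 0.10334491
0.56145707 0.10622105
0.54169322 0.10892303
0.52184736 0.11143898
0.50195124 0.11375753
0.48203690 0.11586782
0.46213658 0.11775957
0.44228269 0.11942315
0.42250774 0.12084966
0.40284430 0.12203097
0.38293962 0.12291865
0.36315141 0.12344194
0.34357178 0.12359797
0.32423676 0.12338656
0.30518213 0.12280929
0.28644328 0.12186957
0.26805508 0.12057259
0.25005173 0.11892536
0.23246670 0.11693665
0.21533252 0.11461693
0.19868074 0.11197836
0.18254175 0.10903463
0.16694473 0.10580093
0.15191752 0.10229379
0.13748653 0.09853096
0.12367670 0.09453123
0.11051139 0.09031434
0.09801235 0.08590069
0.08619972 0.08131125
0.07509192 0.07656732
0.06470570 0.07169032
0.05505615 0.06670159
0.04615663 0.06162217
0.03801887 0.05647261
0.03065297 0.05127277
0.02406742 0.04604155
0.01826914 0.04079681
0.01326354 0.03555509
0.00905458 0.03033150
0.00564476 0.02513955
0.00303523 0.01999100
0.00122580 0.01489580
0.00021497 0.00986192
0.00000000 0.00489535
0.00057691 0.00000000
0.00192435 -0.00474123
0.00401975 -0.00924657
0.00685557 -0.01351550
0.01042315 -0.01754762
0.01471270 -0.02134276
0.01971339 -0.02490092
0.02541339 -0.02822234
0.03179994 -0.03130755
0.03885942 -0.03415736
0.04657741 -0.03677296
0.05493879 -0.03915596
0.06392780 -0.04130842
0.07352812 -0.04323295
0.08372295 -0.04493272
0.09449507 -0.04641156
0.10582694 -0.04767397
0.11770069 -0.04872518
0.13009825 -0.04957119
0.14300135 -0.05021880
0.15639154 -0.05067562
0.17025026 -0.05095006
0.18455881 -0.05105137
0.19929838 -0.05098960
0.21445002 -0.05077553
0.22999468 -0.05042071
0.24591309 -0.04993731
0.26218583 -0.04933814
0.27879325 -0.04863649
0.29571542 -0.04784608
0.31293212 -0.04698095
0.33042278 -0.04605533
0.34816642 -0.04508356
0.36614165 -0.04407990
0.38432661 -0.04305848
0.40275485 -0.04203231
0.42172496 -0.04095510
0.44082464 -0.03980093
0.46002650 -0.03858024
0.47930284 -0.03730323
0.49862567 -0.03597976
0.51796672 -0.03461927
0.53729753 -0.03323077
0.55658943 -0.03182272
0.57581363 -0.03040300
0.59494123 -0.02897890
0.61394328 -0.02755711
0.63279084 -0.02614366
0.65145499 -0.02474397
0.66990694 -0.02336285
0.68811801 -0.02200450
0.70605973 -0.02067258
0.72370388 -0.01937022
0.74102253 -0.01810006
0.75798809 -0.01686432
0.77457336 -0.01566485
0.79075162 -0.01450315
0.80649661 -0.01338046
0.82178263 -0.01229779
0.83658456 -0.01125599
0.85087793 -0.01025577
0.86463897 -0.00929777
0.87784464 -0.00838257
0.89047268 -0.00751074
0.90250169 -0.00668286
0.91391113 -0.00589955
0.92468141 -0.00516144
0.93479393 -0.00446922
0.94423111 -0.00382365
0.95297644 -0.00322550
0.96101455 -0.00267559
0.96833123 -0.00217475
0.97491347 -0.00172383
0.98074953 -0.00132364
0.98582895 -0.00097498
0.99014258 -0.00067858
0.99368264 -0.00043510
0.99644271 -0.00024510
0.99841778 -0.00010905
0.99960427 -0.00002728
1.00000000 0.00000000
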