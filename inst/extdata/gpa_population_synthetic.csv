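"Y","X1","X2"
3.5643,14.5686,21.8673
2.0248,26.5512,18.8675
0.4973,18.0139,32.01
3.3891,43.9288,30.0774
2.6231,14.7242,-1.6414
5.5754,39.3841,48.9812
2.1433,11.2044,9.4801
5.4228,27.2078,42.7602
3.0242,18.1782,22.5714
2.9063,13.9327,4.2458
4.2676,27.6814,30.1893
3.0011,23.9242,14.617
4.6701,35.0749,8.6361
4.8436,35.9459,13.7378
2.6755,31.859,9.7944
4.9035,28.0273,54.7606
4.728,22.0198,60.2035
4.4819,29.8507,35.6193
5.2432,21.4611,57.0351
4.6875,39.0046,35.6848
3.003,30.2277,-16.1711
3.2038,25.215,51.6033
5.7942,31.8804,36.1341
4.1257,10.1256,68.0925
2.9456,30.7984,32.6083
0.544,20.5481,28.7835
2.6311,16.0294,29.2678
2.2335,44.3094,23.4889
6.3016,36.3025,37.9723
8.391,49.5144,26.9066
3.2371,21.3827,-10.8517
5.8937,32.8881,33.8753
2.3192,24.4416,9.0712
3.6309,28.7195,4.2142
2.613,17.9096,21.2985
2.9572,33.6181,11.1157
4.5762,21.9712,6.8668
5.6412,27.8171,-2.0997
5.3783,26.3357,22.4165
3.4944,35.7917,57.4037
4.4412,26.3727,-13.9993
4.4247,46.7114,11.7785
4.4534,30.2251,26.1823
3.358,33.1323,-5.8171
4.2255,24.4147,34.4937
4.8967,38.7901,0.2142
7.7709,18.3553,16.8929
5.55,34.4394,7.4521
4.282,25.6084,10.6407
4.9978,31.408,8.5996
4.8453,26.2009,2.2957
1.84,21.5256,20.2082
2.9839,30.3202,13.1418
5.734,15.5731,34.4532
6.4213,30.8431,-32.4954
7.613,37.4732,12.124
0.1713,22.7753,40.9979
3.009,26.0482,29.3255
4.2232,26.0477,11.086
4.9005,24.0041,37.6763
5.3997,32.7434,22.0655
3.2214,47.067,14.5114
0.4165,10.7818,33.83
1.6982,29.9847,22.189
5.4958,24.1858,30.8726
3.4802,33.1488,10.0652
5.1544,31.7042,4.0178
3.0715,24.9453,30.9165
5.5014,35.3385,0.5653
5.2923,41.7327,4.8144
1.1761,35.5219,-5.5818
2.1281,25.9067,-7.1676
3.5624,29.9619,31.8132
2.2242,29.9057,20.9557
4.8636,20.4859,12.5703
3.5696,28.6216,44.6987
3.4927,24.7309,14.9797
3.0429,24.2343,19.0263
3.7366,28.3634,-0.375
1.7793,22.5913,3.4212
4.0816,30.551,30.5586
6.6922,33.6976,42.8323
3.503,18.7975,-23.9221
4.5402,12.67,21.1247
3.9498,17.534,28.5416
4.2351,23.0249,10.6192
5.4098,45.1282,20.6142
2.8212,13.8811,4.3934
2.3258,19.2979,24.5048
0.4149,29.7243,34.9999
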