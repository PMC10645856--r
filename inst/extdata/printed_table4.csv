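var_s,n,estimator,mean,mse,pre,vartheta
0.2,200,t0,12.6563,4.1872,100.00,0.4126
0.2,200,ratio,12.7547,4.1573,100.72,0.4097
0.2,200,gratio,12.6568,4.1013,102.09,0.4042
0.2,200,t1D,12.0520,3.9767,105.29,0.3919
0.2,500,t0,12.6540,1.2985,100.00,0.1280
0.2,500,ratio,12.6910,1.0253,126.65,0.1010
0.2,500,gratio,12.6539,1.0065,129.01,0.0980
0.2,500,t1D,12.0586,0.2382,545.13,0.0235
0.5,200,t0,14.6764,4.1979,100.00,0.4137
0.5,200,ratio,14.8676,4.0264,104.26,0.3968
0.5,200,gratio,14.6795,3.9598,106.01,0.3902
0.5,200,t1D,13.0802,2.9901,140.39,0.0976
0.5,500,t0,14.7046,1.4063,100.00,0.1386
0.5,500,ratio,14.7376,1.0221,137.59,0.1007
0.5,500,gratio,14.7047,0.9945,141.41,0.0980
0.5,500,t1D,13.0697,0.2428,579.20,0.0239
1,200,t0,13.1945,3.2376,100.00,0.3191
1,200,ratio,13.3712,3.2163,100.66,0.3170
1,200,gratio,13.1975,3.1964,101.29,0.3150
1,200,t1D,12.0749,0.9605,337.07,0.0947
1,500,t0,13.1984,1.3192,100.00,0.1300
1,500,ratio,13.2229,0.8057,163.73,0.0794
1,500,gratio,13.1979,0.7942,166.10,0.0783
1,500,t1D,12.0569,0.2420,545.12,0.0238
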