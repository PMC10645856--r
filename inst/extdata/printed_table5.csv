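var_s,n,estimator,mean,mse,pre,vartheta
0.2,200,t0,8.1658,1.5367,100.00,0.2136
0.2,200,ratio,8.2248,1.4245,107.88,0.1980
0.2,200,gratio,8.1710,1.3286,115.66,0.1847
0.2,200,t1D,8.0373,1.1215,137.02,0.1559
0.2,500,t0,8.1555,0.3809,100.00,0.0529
0.2,500,ratio,8.1822,0.3570,106.69,0.0496
0.2,500,gratio,8.1582,0.3324,114.59,0.0462
0.2,500,t1D,8.0517,0.2871,132.67,0.0399
0.5,200,t0,8.9991,2.1105,100.00,0.2934
0.5,200,ratio,9.0607,1.8331,115.13,0.2548
0.5,200,gratio,9.0032,1.7227,122.51,0.2395
0.5,200,t1D,8.0269,1.1276,187.17,0.1567
0.5,500,t0,8.9905,0.5165,100.00,0.0718
0.5,500,ratio,9.0144,0.4564,113.17,0.0634
0.5,500,gratio,8.9923,0.4291,120.37,0.0596
0.5,500,t1D,8.0471,0.2798,184.60,0.0389
1,200,t0,8.7447,2.7373,100.00,0.3805
1,200,ratio,8.8042,2.6687,102.57,0.3710
1,200,gratio,8.7519,2.5569,107.06,0.3554
1,200,t1D,8.0489,1.1238,243.58,0.1562
1,500,t0,8.7367,0.6678,100.00,0.0928
1,500,ratio,8.7636,0.6414,104.12,0.0892
1,500,gratio,8.7390,0.6144,108.69,0.0854
1,500,t1D,8.0495,0.2794,239.01,0.0388
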