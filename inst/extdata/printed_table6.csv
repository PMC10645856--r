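var_s,n,estimator,population,mean,mse,pre,vartheta
0.2,200,tNP1,I,12.8756,3.3689,100.00,0.5960
0.2,200,tNP2,I,13.0140,3.5686,94.40,0.6313
0.2,200,t1N,I,11.0777,1.0035,335.71,0.1775
0.2,500,tNP1,I,12.8432,0.8166,100.00,0.1445
0.2,500,tNP2,I,12.8931,1.1165,73.14,0.1975
0.2,500,t1N,I,11.0683,0.2599,314.20,0.0460
0.5,200,tNP1,I,13.4345,4.4759,100.00,0.7918
0.5,200,tNP2,I,13.5454,5.0172,89.21,0.8876
0.5,200,t1N,I,12.0603,1.0186,439.42,0.1802
0.5,500,tNP1,I,13.4065,1.0886,100.00,0.1926
0.5,500,tNP2,I,13.4385,1.2013,90.62,0.2125
0.5,500,t1N,I,12.0664,0.2485,438.07,0.0440
1,200,tNP1,I,13.9783,4.5249,100.00,0.8005
1,200,tNP2,I,14.0973,4.8623,93.06,0.8602
1,200,t1N,I,13.0412,1.3838,326.99,0.2448
1,500,tNP1,I,13.9681,1.0967,100.00,0.1940
1,500,tNP2,I,13.9922,1.3800,79.47,0.2441
1,500,t1N,I,13.0686,0.3347,327.67,0.0592
0.2,200,tNP1,II,7.9867,1.3649,100.00,0.2759
0.2,200,tNP2,II,8.0386,1.2930,105.56,0.2613
0.2,200,t1N,II,7.0332,1.1664,117.02,0.2358
0.2,500,tNP1,II,7.5139,0.3972,100.00,0.0803
0.2,500,tNP2,II,7.5327,0.3666,108.35,0.0741
0.2,500,t1N,II,7.0452,0.2466,161.07,0.0498
0.5,200,tNP1,II,8.0543,1.8112,100.00,0.3661
0.5,200,tNP2,II,8.1007,1.5241,118.84,0.3080
0.5,200,t1N,II,7.4002,1.1855,152.78,0.2396
0.5,500,tNP1,II,8.0695,0.4521,100.00,0.0914
0.5,500,tNP2,II,8.0792,0.3813,118.57,0.0771
0.5,500,t1N,II,7.0388,0.2986,151.41,0.0604
1,200,tNP1,II,7.6827,1.9927,100.00,0.4028
1,200,tNP2,II,7.7180,1.6920,117.77,0.3420
1,200,t1N,II,7.1079,1.2108,164.58,0.2447
1,500,tNP1,II,7.7117,0.5027,100.00,0.1016
1,500,tNP2,II,7.7162,0.4298,116.96,0.0869
1,500,t1N,II,7.0337,0.2945,170.70,0.0595
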