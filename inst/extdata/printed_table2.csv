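n,model,estimator,mean,mse
20,dp,t0,5.3726,8.2592
20,dp,ratio,7.9481,4.2433
20,dp,t1D,3.4357,3.3778
20,np,tNP1,73.5542,229.6445
20,np,tNP2,107.2465,78.2292
20,np,t1N,47.0329,64.1311
38,dp,t0,5.3279,3.4451
38,dp,ratio,6.4387,2.3176
38,dp,t1D,3.4072,1.4090
38,np,tNP1,73.5636,96.6005
38,np,tNP2,87.7502,96.1805
38,np,t1N,47.0429,39.5865
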