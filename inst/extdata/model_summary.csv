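parameter,family,ranking,model,best_R2,reduced_R2,n_best,n_reduced
LAI,CI,MRMR,XGBoost,0.599,0.569,14,5
LAI,MI,GRA,XGBoost,0.716,0.680,43,11
PRI,CI,GRA,RFR,0.284,0.270,19,17
PRI,MI,GRA,XGBoost,0.643,0.611,55,53
PhiPSII,CI,PCA,XGBoost,0.920,0.874,22,3
PhiPSII,MI,GRA,XGBoost,0.919,0.873,36,3
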