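name,theta_res,theta_sat,alpha,n,K_sat,lam
sand,0.045,0.43,0.15,3.0,1000,0.5
loam,0.08,0.43,0.04,1.6,50,0.5
clay,0.1,0.40,0.01,1.1,10,0.5
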