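parameter,r2v,rmsep,rpd_p,sel_v,prl_p,rer_p
CP,0.99,0.57,9.37,1.41,0.41,35.72
NDF,0.91,2.60,3.44,1.77,1.47,12.03
ADF,0.95,1.32,4.40,1.29,1.02,15.64
WSC,0.91,2.56,3.39,1.64,1.56,13.50
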