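parameter,scm,windows,rank,r2cv,rmsecv,rpd_c,sel_c,prl_c,rer_cv
CP,FD+MSC,4247-6102,10,0.99,0.68,8.58,1.56,0.43,38.57
NDF,MSC,4247-5450,7,0.94,2.23,4.25,1.62,1.38,17.57
ADF,FD,4247-4602;5446-6102,6,0.92,1.68,3.64,1.43,1.17,14.59
WSC,MMN,4247-4602;5446-6102,7,0.88,3.11,3.10,1.66,1.88,15.30
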