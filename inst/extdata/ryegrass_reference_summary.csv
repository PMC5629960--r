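parameter,set,n,mean,sd,min,max
CP,calibration,93,12.94,5.82,4.45,30.60
NDF,calibration,93,40.47,9.48,21.29,60.47
ADF,calibration,93,22.92,6.12,11.66,36.17
WSC,calibration,93,19.93,9.63,3.95,51.52
CP,validation,30,12.80,5.36,5.10,25.53
NDF,validation,30,40.48,8.95,24.14,55.41
ADF,validation,30,22.92,5.81,13.23,33.88
WSC,validation,30,19.65,8.68,5.33,39.90
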