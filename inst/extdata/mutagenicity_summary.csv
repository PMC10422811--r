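treatment,mean,sd,n
vehicle control,2.57,1.27,7
30 mg/kg,3.80,1.10,5
50 mg/kg,6.20,1.48,5
75 mg/kg,14.0,3.94,5
100 mg/kg,20.0,4.06,5
positive control,25.0,8.91,4
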