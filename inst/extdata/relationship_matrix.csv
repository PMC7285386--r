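,SH,Hyte,Dysl,Diab,FSH,TIA,Smok,AF,Sport,Sleep,Gen,BMIc,Tea,Age,Alco,DT
SH,0,6.84,6.34,5.71,5.71,3.91,4.16,0.45,4.49,0.42,1.74,2.17,0.6,6.84,0.7,0.96
Hyte,6.84,0,6.34,5.71,4.95,3.91,4.16,0.45,4.49,0.42,1.74,2.17,0.6,6.84,0.7,0.96
Dysl,6.34,6.34,0,5.46,4.95,3.66,4.16,0.45,4.49,0.42,1.74,2.17,0.6,6.34,0.7,0.96
Diab,5.71,5.71,5.46,0,4.64,3.46,4.16,0.45,3.82,0.42,1.43,2.17,0.6,5.71,0.7,0.96
FSH,5.71,4.95,4.95,4.64,0,3.29,3.85,0.45,3.98,0.27,1.43,2.17,0.6,4.95,0.7,0.96
TIA,3.91,3.91,3.66,3.46,3.29,0,3.03,0.33,2.9,0.08,1.05,2.17,0.48,3.91,0.4,0.96
Smok,4.16,4.16,4.16,4.16,3.85,3.03,0,0.2,3.44,0.42,1.05,2.17,0.48,4.16,0.7,0.96
AF,0.45,0.45,0.45,0.45,0.45,0.33,0.2,0,0.2,0,0,0,0.13,0.45,0,0
Sport,4.49,4.49,4.49,3.82,3.98,2.9,3.44,0.2,0,0.27,1.74,2.17,0.48,4.49,0.7,0.96
Sleep,0.42,0.42,0.42,0.42,0.27,0.08,0.42,0,0.27,0,0.08,0.08,0,0.42,0.19,0
Gen,1.74,1.74,1.74,1.43,1.43,1.05,1.05,0,1.74,0.08,0,1.05,0.22,1.74,0.22,0.62
BMIc,2.17,2.17,2.17,2.17,2.17,2.17,2.17,0,2.17,0.08,1.05,0,0.38,2.17,0.4,0.86
Tea,0.6,0.6,0.6,0.6,0.6,0.48,0.48,0.13,0.48,0,0.22,0.38,0,0.6,0.14,0.38
Age,6.84,6.84,6.34,5.71,4.95,3.91,4.16,0.45,4.49,0.42,1.74,2.17,0.6,0,0.7,0.96
Alco,0.7,0.7,0.7,0.7,0.7,0.4,0.7,0,0.7,0.19,0.22,0.4,0.14,0.7,0,0.22
DT,0.96,0.96,0.96,0.96,0.96,0.96,0.96,0,0.96,0,0.62,0.86,0.38,0.96,0.22,0
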