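factor,depth,frequency
SH,0,1
Hyte,2,2
Dysl,3,2
Dysl,4,1
Diab,3,4
Diab,4,2
Diab,6,1
FSH,5,4
FSH,7,1
TIA,3,1
TIA,4,1
TIA,5,1
TIA,6,2
TIA,7,2
Smok,5,1
Smok,6,2
Smok,7,1
AF,6,7
AF,9,2
Sport,4,1
Sport,7,1
Sport,8,3
Sleep,6,1
Sleep,9,1
Sleep,11,1
Gen,5,1
Gen,6,1
Gen,10,3
Gen,11,2
BMIc,9,3
BMIc,10,1
Tea,7,1
Tea,9,1
Tea,12,1
Age,1,1
Age,8,2
Age,10,1
Age,11,3
Age,12,3
Age,14,1
Alco,8,1
Alco,10,2
Alco,12,1
Alco,13,1
DT,10,1
DT,11,3
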