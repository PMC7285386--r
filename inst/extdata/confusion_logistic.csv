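,H,M,Y,T,N,L
H,1289,124,0,1,0,1
M,97,1446,1,1,1,0
Y,0,0,164,0,0,1
T,5,0,1,46,1,0
N,0,0,0,0,690,244
L,0,1,0,0,214,563
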