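,H,M,Y,T,N,L
H,1288,127,0,0,0,0
M,44,1502,0,0,0,0
Y,0,0,165,0,0,0
T,2,0,0,51,0,0
N,0,0,0,0,679,255
L,0,0,0,0,182,596
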