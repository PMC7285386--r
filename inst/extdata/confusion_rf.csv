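,H,M,Y,T,N,L
H,1300,115,0,0,0,0
M,72,1473,0,0,1,0
Y,6,0,158,0,0,1
T,24,6,0,11,3,9
N,0,0,0,0,699,235
L,0,0,0,0,239,539
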