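class,a,E,j,!,L,N,V,R
a,150,0,0,0,0,0,0,0
E,0,106,0,1,0,0,0,0
j,0,0,228,0,0,0,0,0
!,0,0,0,470,0,0,0,0
L,0,0,0,1,2784,0,0,0
N,0,0,0,0,0,77,0,0
V,0,0,0,0,0,0,73,0
R,0,0,1,0,0,0,0,1802
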