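class,count
N,74758
L,8072
R,7255
V,7123
!,472
j,229
a,150
E,106
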