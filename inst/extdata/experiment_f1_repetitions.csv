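test,experiment1,experiment2,experiment3,experiment4
1,99.74,99.74,99.50,99.69
2,99.84,99.70,99.56,99.47
3,99.73,99.74,99.30,99.61
4,99.76,99.73,99.51,99.68
5,99.82,99.76,99.65,99.52
6,99.61,99.65,99.27,99.56
7,99.26,99.88,99.62,99.54
8,99.93,99.78,99.14,99.68
9,99.62,99.87,99.81,99.66
10,99.41,99.83,99.62,99.66
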