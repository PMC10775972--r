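a12: 0.08
a14: 1.24
a32: 1.09
a65: 1.0
a_svp: 1.0
bm: 1.29
bm21: 2.89
bm34: 1.58
bm43: 2.84
bm44: 0.6
bm54: 1.0
b: 0.9
b21: 1.0
b34: 1.0
b43: 1.0
b44: 1.0
b54: 1.0
k: 1.0
'n': 4.0
S: 1.0
c: 0.0074
svp: 0.5
co2: 430.0
D: 0.0668
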