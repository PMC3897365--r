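a_p: 0.154
b_p: 16.699999999999999
d_p: 0.0717
a: 0.154
b: 12.5
d: 0.0717
m: 0.0229
alpha: 0.666666666666667
p: 8.3e-06
k: 0.38
e: 7.5
V0: 1.0e-06
K0: 1.0
Vm: 1.0
D2: 0.156
Vd: 7000.0
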