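element,vdw_volume,polarizability,estate
H,0.352,0.379,0.250
B,1.441,1.722,1.000
C,1.000,1.000,1.000
N,0.759,0.625,2.000
O,0.714,0.456,3.000
F,0.646,0.316,4.000
Si,1.885,3.057,0.722
P,1.188,2.063,1.167
S,1.188,1.648,1.611
Cl,1.091,1.239,2.056
Br,1.290,1.733,1.375
I,1.581,3.040,1.060
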