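subject,age_years,height_m,weight_kg
1,21,1.79,83
2,22,1.72,54
3,22,1.70,68
4,23,1.79,67
5,22,1.70,85
6,21,1.65,55
7,21,1.69,63
8,22,1.70,60
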