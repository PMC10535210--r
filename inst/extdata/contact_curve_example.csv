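penetration_m,force_N
0,0
0.03,6000
0.10,30000
0.20,80000
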