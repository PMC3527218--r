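label,bt_offset,bb_offset,wm_offset
A1,0,0,0
A2,0,0,0
A3,0,0,0
A4,0,0,0
alpha,0,0,0
B1,0,0,0
B2,0,0,0
B3,0,0,0
B4,0,0,0
beta,0,0,0
C1,0,0,0
C2,0,0,0
C3,0,0,0
C4,0,0,0
gamma,0,0,0
D1,0,0,0
D2,68,59,-7
D3,0,0,0
D4,0,0,0
delta,0,0,0
E1,0,0,0
E2,0,0,0
E3,0,0,0
E4,0,0,0
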