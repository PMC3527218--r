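label,se,sd,rmse
A1,27,95,179
A2,24,80,170
A3,27,89,166
A4,26,86,166
alpha,40,138,211
B1,19,65,106
B2,14,48,101
B3,15,51,108
B4,19,65,131
beta,36,124,158
C1,27,92,106
C2,20,69,104
C3,22,75,102
C4,30,102,167
gamma,42,139,176
D1,30,105,153
D2,28,98,121
D3,24,83,110
D4,27,95,150
delta,33,114,203
E1,20,71,148
E2,23,81,136
E3,26,91,160
E4,24,85,168
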