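param,bag1,bag2,chain
tau,0.149,0.205,0.0001
freq,60,60,90
p,2,2,2
beta0,0.0605,0.0822,0.0822
beta1,0.2592,0,0
beta2,0,-0.046,-0.069
Gamma1,0.0289,0,0
Gamma2,0,0.0636,0.0954
C_L,1,1,1
C_S,0.42,0.42,0.42
K_SR,10.4689,10.4689,10.4689
K_PR,0.15,0.15,0.15
M,0.0002,0.0002,0.0002
L0_SR,0.04,0.04,0.04
L0_PR,0.76,0.76,0.76
LN_SR,0.0423,0.0423,0.0423
LN_PR,0,0.89,0.89
R,0.46,0.46,0.46
a_pow,0.3,0.3,0.3
G_pri,20000,10000,10000
G_sec,0,7250,7250
X,0,0.7,0.7
L_sec,0,0.04,0.04
S_occl,0.156,0.156,0.156
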