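muscle,F0_N,L0_cm,mass_kg,k_pe,b_pe,strain,alpha0_deg,Lt1_cm,c_t,k_t,L_r
SO,3586,4.90,0.53,5,0.005,0.50,28.30,28.90,0.005,27.80,0.964
MG,1306,5.70,0.22,5,0.005,0.50,9.90,42.40,0.005,27.80,0.964
LG,606,6.40,0.12,5,0.005,0.50,12,41.30,0.005,27.80,0.964
TA,674,6.80,0.15,5,0.005,0.50,9.60,24.90,0.005,27.80,0.964
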