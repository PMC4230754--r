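parameter,value_lo,value_hi,unit
v_Ia,62,67,m/s
v_Ib,56,62,m/s
v_II,30,35,m/s
conn_Ia_MN_hom,0.80,0.80,fraction
conn_Ia_MN_syn,0.15,0.15,fraction
conn_Ia_IN,0.70,0.70,fraction
conn_Ib_IN,0.30,0.30,fraction
conn_II_IN,0.30,0.30,fraction
conn_IaIN_MN,0.15,0.15,fraction
conn_IbIN_MN,0.10,0.10,fraction
conn_gIIIN_MN,0.20,0.20,fraction
g_Ia_MN,600,600,nS
g_Ia_IN,600,600,nS
g_II_IN,450,450,nS
g_Ib_IN,300,300,nS
g_IN_MN,300,300,nS
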