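muscle,n_Ia,n_II,n_Ib
SO,400,500,300
MG,160,200,120
LG,160,200,120
TA,280,350,140
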