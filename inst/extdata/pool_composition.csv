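muscle,n_S,n_FR,n_FF
SO,800,50,50
MG,300,150,150
LG,130,65,65
TA,250,50,50
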