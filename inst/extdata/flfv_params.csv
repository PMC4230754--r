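fibre,fl_beta,fl_omega,fl_rho,fv_vmax,fv_cv0,fv_cv1,fv_av0,fv_av1,fv_av2,fv_bv
slow,2.30,1.12,1.62,-7.88,5.88,0,-4.70,8.41,-5.34,0.35
fast,1.55,0.75,2.12,-9.15,-5.70,9.18,-1.53,0,0,0.69
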