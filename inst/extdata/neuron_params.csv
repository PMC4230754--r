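type,rin_mohm_lo,rin_mohm_hi,tau_ms_lo,tau_ms_hi,thr_mv_lo,thr_mv_hi,ahp_tau_ms_lo,ahp_tau_ms_hi,ahp_gfac,v_axon_lo,v_axon_hi
S,1.40,1.10,10,8,8,12,80,50,1.2,44,51
FR,1.05,0.85,8,7,12,15,35,25,1.0,51,52
FF,0.80,0.55,7,6,15,18,25,15,0.8,52,53
IN,10,8,5,5,10,20,30,20,1.0,NA,NA
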