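type,tc_s_lo,tc_s_hi,ftet_hz_lo,ftet_hz_hi,emg_lambda_ms_lo,emg_lambda_ms_hi
S,0.100,0.060,15,30,6,4
FR,0.055,0.040,30,45,4,3
FF,0.040,0.025,45,60,3,2.5
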