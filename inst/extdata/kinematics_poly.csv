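muscle,a0,a1,a2,a3,a4,b0,b1,b2,b3,b4
SO,32.30,7.22e-2,-2.24e-4,-3.15e-6,9.27e-9,-4.10,2.57e-2,5.45e-4,-2.22e-6,-5.50e-9
MG,46.40,7.48e-2,-1.13e-4,-3.50e-6,7.35e-9,-4.30,1.30e-2,6.08e-4,-1.87e-6,-1.02e-9
LG,45.50,7.62e-2,-1.25e-4,-3.55e-6,7.65e-9,-4.40,1.44e-2,6.18e-4,-1.94e-6,-1.02e-9
TA,30.60,-7.44e-2,-1.41e-4,2.42e-6,1.50e-9,4.30,1.66e-2,-3.89e-4,-4.45e-6,-4.34e-9
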