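factor,ref,k_m,tau,gof_printed
power,759.42,0.14,11.68,0.054598
ethanol,2315.22,0.13,10.91,0.070991
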