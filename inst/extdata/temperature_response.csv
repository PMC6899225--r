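temperature_C,max_strain,mean_stiffness_MPa
20,0.264,5280
55,0.257,3640
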