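thread_type,diameter_um,modulus_MPa,tension_uN,breaking_strain
spiral,2.40,500,10,1.600
radial,3.93,2600,132,0.462
frame,7.23,5555,924,0.225
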