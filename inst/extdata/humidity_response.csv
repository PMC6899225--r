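humidity_percent,max_strain,mean_stiffness_MPa
15,0.246,4170
50,0.270,3440
70,1.059,680
100,1.953,140
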