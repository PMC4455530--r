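scenario,charge_group,energy_bin,hzetrn_mGy,model_mGy
habitat,Z=3-8,<500,14.7,14.2
habitat,Z=3-8,500-900,2.9,3.0
habitat,Z=3-8,>900,5.2,5.6
habitat,Z=9-14,<500,4.3,4.6
habitat,Z=9-14,500-900,1.4,1.4
habitat,Z=9-14,>900,2.9,2.7
habitat,Z=15-28,<500,3.3,3.3
habitat,Z=15-28,500-900,1.2,1.2
habitat,Z=15-28,>900,2.9,2.9
transfer,Z=3-8,<500,11.3,10.9
transfer,Z=3-8,500-900,1.7,1.8
transfer,Z=3-8,>900,3.3,3.6
transfer,Z=9-14,<500,1.7,1.8
transfer,Z=9-14,500-900,0.7,0.7
transfer,Z=9-14,>900,1.6,1.5
transfer,Z=15-28,<500,1.1,1.1
transfer,Z=15-28,500-900,0.5,0.5
transfer,Z=15-28,>900,1.4,1.3
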