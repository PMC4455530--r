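scenario,charge_group,dose_fraction,dose_mGy
habitat,Z=1,0.60,120.8
habitat,Z=2,0.21,42.5
habitat,Z=3-8,0.11,22.7
habitat,Z=9-14,0.04,8.5
habitat,Z=15-28,0.04,7.4
transfer,Z=1,0.70,145.0
transfer,Z=2,0.19,38.5
transfer,Z=3-8,0.08,16.3
transfer,Z=9-14,0.02,4.0
transfer,Z=15-28,0.01,2.9
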