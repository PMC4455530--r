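ion,energy_MeVu,sigma_cm2_per_g
16O,500,0.0668
16O,900,0.0706
16O,1500,0.0722
28Si,500,0.0916
28Si,900,0.0966
28Si,1500,0.0987
56Fe,500,0.1307
56Fe,900,0.1366
56Fe,1500,0.1392
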