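ion,energy_MeVu,dose_fraction_habitat,xpe_habitat_gcm2,dose_fraction_transfer,xpe_transfer_gcm2,sigma_cm2_per_g
16O,500,0.305,17.8,0.169,26.6,0.0668
28Si,500,0.299,13.2,0.236,15.7,0.0916
56Fe,500,0.410,6.8,0.309,9.0,0.1307
16O,900,0.447,18.0,0.382,20.5,0.0706
28Si,900,0.306,21.5,0.250,23.5,0.0966
56Fe,900,0.430,8.2,0.327,12.9,0.1366
16O,1500,0.455,17.2,0.396,19.5,0.0722
28Si,1500,0.290,21.5,0.240,24.0,0.0987
56Fe,1500,0.455,7.4,0.350,12.0,0.1392
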