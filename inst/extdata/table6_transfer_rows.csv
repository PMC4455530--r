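ion,energy_MeVu,xpe_gcm2,eout_MeVu,dose_ratio,role,share,dose_mGy,per_gy_fluence,fluence_per_um2
16O,500,0,NA,1,primary,0.076,0.82,0.353,2.89e-4
16O,500,26.6,10,1.22,fragments,0.924,9.9,0.353,2.86e-3
16O,900,0,NA,1,primary,0.237,0.38,0.428,1.61e-4
16O,900,20.5,484,0.61,fragments,0.763,1.21,0.428,8.48e-4
16O,1500,0,NA,1,primary,0.252,0.79,0.465,3.68e-4
16O,1500,19.5,1097,0.57,fragments,0.748,2.35,0.465,1.90e-3
28Si,500,0,NA,1,primary,0.096,0.19,0.115,2.24e-5
28Si,500,15.7,0,1.4,fragments,0.904,1.82,0.115,1.50e-4
28Si,900,0,NA,1,primary,0.17,0.13,0.140,1.84e-5
28Si,900,23.5,249,0.46,fragments,0.83,0.64,0.140,1.94e-4
28Si,1500,0,NA,1,primary,0.176,0.33,0.152,4.96e-5
28Si,1500,24,839,0.37,fragments,0.824,1.53,0.152,6.37e-4
56Fe,500,0,NA,1,primary,0.136,0.15,0.034,4.98e-6
56Fe,500,9,4,1.3,fragments,0.864,0.94,0.034,2.43e-5
56Fe,900,0,NA,1,primary,0.208,0.1,0.041,4.11e-6
56Fe,900,12.9,273,0.57,fragments,0.792,0.39,0.041,2.76e-5
56Fe,1500,0,NA,1,primary,0.233,0.33,0.044,1.44e-5
56Fe,1500,12,902,0.5,fragments,0.767,1.08,0.044,9.45e-5
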