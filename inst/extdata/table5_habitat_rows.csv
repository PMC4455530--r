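ion,energy_MeVu,xpe_gcm2,eout_MeVu,dose_ratio,role,share,dose_mGy,per_gy_fluence,fluence_per_um2
16O,500,0,NA,1,primary,0.164,2.25,0.353,7.94e-4
16O,500,17.8,119,0.86,fragments,0.836,11.48,0.353,4.69e-3
16O,900,0,NA,1,primary,0.271,0.73,0.428,3.12e-4
16O,900,18,516,0.64,fragments,0.729,1.96,0.428,1.30e-3
16O,1500,0,NA,1,primary,0.282,1.36,0.465,6.34e-4
16O,1500,17.2,1127,0.61,fragments,0.718,3.48,0.465,2.64e-3
28Si,500,0,NA,1,primary,0.151,0.74,0.115,8.50e-5
28Si,500,13.2,52,0.99,fragments,0.849,4.16,0.115,4.84e-4
28Si,900,0,NA,1,primary,0.206,0.32,0.140,4.53e-5
28Si,900,21.5,286,0.48,fragments,0.794,1.25,0.140,3.61e-4
28Si,1500,0,NA,1,primary,0.207,0.68,0.152,1.03e-4
28Si,1500,21.5,886,0.4,fragments,0.793,2.61,0.152,9.91e-4
56Fe,500,0,NA,1,primary,0.207,0.69,0.034,2.33e-5
56Fe,500,6.8,85,0.98,fragments,0.793,2.65,0.034,9.03e-5
56Fe,900,0,NA,1,primary,0.256,0.33,0.041,1.32e-5
56Fe,900,8.2,433,0.67,fragments,0.744,0.95,0.041,5.70e-5
56Fe,1500,0,NA,1,primary,0.276,0.83,0.044,3.66e-5
56Fe,1500,7.4,1062,0.65,fragments,0.724,2.18,0.044,1.48e-4
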