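scenario,ion,energy_MeVu,dose_mGy,fluence_per_um2
habitat,p,50,28.05,1.39e-1
habitat,p,100,12.34,1.05e-1
habitat,p,200,13.11,1.81e-1
habitat,p,300,7.91,1.39e-1
habitat,p,400,5.93,1.04e-1
habitat,p,500,4.85,1.09e-1
habitat,p,600,4.1,9.97e-2
habitat,p,800,6.63,1.76e-1
habitat,p,900,2.72,7.46e-2
habitat,p,1000,2.42,6.79e-2
habitat,p,1200,4.09,1.18e-1
habitat,p,1400,3.31,9.79e-2
habitat,p,1600,2.72,8.13e-2
habitat,p,1800,2.27,6.85e-2
habitat,p,2000,1.92,5.81e-2
habitat,p,2500,18.46,5.59e-1
habitat,4He,50,14.54,1.80e-2
habitat,4He,100,4.42,9.36e-3
habitat,4He,200,4.86,1.68e-2
habitat,4He,300,3.07,1.35e-2
habitat,4He,400,2.23,1.14e-2
habitat,4He,500,1.69,9.52e-3
habitat,4He,600,1.32,7.98e-3
habitat,4He,800,1.95,1.30e-2
habitat,4He,900,0.75,5.14e-3
habitat,4He,1000,0.63,4.43e-3
habitat,4He,1200,7.01,5.08e-2
transfer,p,50,40.28,2.00e-1
transfer,p,100,18.58,1.58e-1
transfer,p,200,18.61,2.57e-1
transfer,p,300,9.71,1.71e-1
transfer,p,400,6.53,1.15e-1
transfer,p,500,5.02,1.14e-1
transfer,p,600,4.12,1.00e-1
transfer,p,800,6.5,1.73e-1
transfer,p,900,2.63,7.20e-2
transfer,p,1000,2.32,6.51e-2
transfer,p,1200,3.89,1.13e-1
transfer,p,1400,3.13,9.26e-2
transfer,p,1600,2.56,7.67e-2
transfer,p,1800,2.13,6.45e-2
transfer,p,2000,1.8,5.46e-2
transfer,p,2500,17.21,5.21e-1
transfer,4He,50,15.92,1.97e-2
transfer,4He,100,4.21,8.93e-3
transfer,4He,200,4.09,1.41e-2
transfer,4He,300,2.37,1.04e-2
transfer,4He,400,1.69,8.64e-3
transfer,4He,500,1.27,7.17e-3
transfer,4He,600,0.99,6.00e-3
transfer,4He,800,1.5,1.00e-2
transfer,4He,900,0.6,4.09e-3
transfer,4He,1000,0.5,3.49e-3
transfer,4He,1200,5.38,3.90e-2
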