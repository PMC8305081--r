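x1,x2,x3,ph_mean,ph_sd,tta_pct_mean,tta_pct_sd,viscosity_mpas_mean,viscosity_mpas_sd,ph_n,tta_pct_n,viscosity_mpas_n
0.05,0.05,0.05,3.58,0.15,0.59,0.06,6.68,4.42,3,3,3
0.05,0.05,0.1,3.57,0.16,0.61,0.09,1.32,1.76,3,3,3
0.05,0.1,0.05,3.63,0.18,0.59,0.08,6.48,4.01,3,3,3
0.05,0.1,0.1,3.63,0.2,0.56,0.02,5.72,5.96,3,3,3
0.075,0.075,0.075,3.57,0.16,0.59,0.04,6.71,1.71,3,3,3
0.1,0.05,0.05,3.61,0.17,0.55,0.03,2.11,0.84,3,3,3
0.1,0.05,0.1,3.76,0.11,0.54,0.03,5.17,3.98,3,3,3
0.1,0.1,0.05,3.52,0.14,0.61,0.02,4.62,4.84,3,3,3
0.1,0.1,0.1,3.64,0.2,0.59,0.06,10.67,0.81,3,3,3
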