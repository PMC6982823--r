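exp,P_bar,dp_um,Q_kg_h,G_lito,G_catchpole,G_fit,ksa0e5_lito,ksa0e5_catchpole,ksa0e5_fit,kfa0e3_lito,kfa0e3_catchpole,kfa0e3_fit,dabe9_lito,dabe9_catchpole,dabe9_fit,sh_lito,sh_catchpole,sh_fit,r2_lito,r2_catchpole,r2_fit
1,220,650,0.604,0.36,0.36,0.37,7.48,7.48,7.35,1.41,1.46,0.736,8.63,9.06,2.97,0.24,0.24,0.96,98.478,98.477,98.472
2,220,220,0.602,0.61,0.61,0.61,7.01,7.01,7.01,6.56,6.77,1.72,8.63,9.06,1.06,0.13,0.13,4.16,99.352,99.352,99.355
3,80,650,1.202,0.39,0.39,0.40,0.182,0.182,0.182,0.114,0.118,8.70,38.0,40.2,0.73,0.45,0.44,0.06,99.716,99.716,99.718
4,80,650,1.209,0.36,0.36,0.37,0.107,0.107,0.107,0.114,0.119,8.95,38.0,40.2,0.76,0.45,0.44,0.05,99.632,99.632,99.626
5,80,220,0.602,0.52,0.52,0.52,9.28,9.28,9.30,0.355,0.369,3.42,38.0,40.2,1.04,0.16,0.16,1.24,99.297,99.297,99.357
6,80,650,0.603,0.44,0.44,0.45,7.58,7.58,7.58,7.63,7.93,4.03,38.0,40.2,13.3,0.30,0.30,0.13,98.302,98.301,98.322
7,140,650,1.204,0.35,0.35,0.37,7.83,7.84,7.71,2.67,2.77,1.26,10.7,11.3,3.15,0.37,0.37,0.40,98.548,98.541,98.663
8,180,220,0.913,0.62,0.62,0.66,2.75,2.75,2.31,9.19,9.51,0.773,9.4,9.9,6.61,0.17,0.16,5.84,98.268,98.268,99.137
9,180,220,0.904,0.54,0.54,0.59,2.32,2.32,1.91,9.14,9.46,0.929,9.4,9.9,8.79,0.17,0.16,5.11,98.421,98.421,99.019
10,180,650,0.908,0.23,0.23,0.23,0.108,0.108,0.108,1.97,2.04,2.64,9.4,9.9,13.4,0.31,0.31,0.29,99.381,99.381,99.381
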