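compound,RI,exp1,exp2,exp3,exp4,exp5,exp6,exp7,exp8,exp9,exp10
alpha-pinene,939,33.30,30.00,34.21,30.10,33.21,32.10,34.31,31.10,32.41,32.1
terpinene-4-ol,1178,13.04,13.24,13.08,13.68,13.02,12.01,12.77,12.06,13.12,12.16
1-8-cineole,1033,5.10,6.10,6.02,6.62,5.85,6.42,5.66,6.11,5.06,7.11
alpha-terpineol,1189,4.61,4.01,4.58,4.88,4.12,4.21,4.06,4.67,4.68,4.55
beta-caryophyllene,1434,4.02,4.92,4.22,4.82,4.88,4.03,4.12,4.43,4.01,4.93
borneol,1165,3.92,3.12,4.62,4.02,4.22,4.12,4.45,4.16,4.85,4.66
others,NA,36.01,38.61,31.27,35.88,34.70,37.11,34.63,37.47,35.87,34.49
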