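volume_m3,H_m,d_m,aspect,fci_usd
0.1,2.01,0.252,8.0,853975
0.2,2.54,0.317,8.0,1378550
0.4,3.19,0.399,8.0,2225400
0.6,3.66,0.457,8.0,2944900
1.0,4.34,0.542,8.0,4191250
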