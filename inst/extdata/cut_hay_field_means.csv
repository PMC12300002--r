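field,acres,n,pfos_mean,pfos_sd,pfda_mean,pfda_sd
2,15,3,3.44,1.47,18.64,4.72
3,1,1,6.89,NA,24.85,NA
6,8,3,5.11,2.59,18.47,1.12
7,13,8,8.47,3.88,11.87,3.18
8,14,5,7.11,3.82,14.21,7.70
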