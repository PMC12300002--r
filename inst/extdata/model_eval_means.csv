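scenario,n,analyte,matrix,measured_mean,measured_sd,modeled_mean,modeled_sd,modeled_min,modeled_max,published_pct_error
2021,1,PFOS,muscle,2.87,NA,2.33,1.12,0.95,6.40,-19
2021,1,PFDA,muscle,4.29,NA,3.61,1.73,1.47,9.90,-16
2022,5,PFOS,muscle,2.25,0.29,1.48,0.73,0.57,4.09,-34
2022,5,PFOS,serum,24.6,2.69,17.6,6.53,7.49,34.3,-29
2022,5,PFDA,muscle,3.30,0.61,1.56,0.78,0.58,4.32,-53
2022,5,PFDA,serum,35.8,5.41,18.6,6.97,7.62,36.3,-48
2023,6,PFOS,serum,12.2,2.24,20.3,7.78,7.91,39.9,67
2023,6,PFDA,serum,14.6,3.93,25.2,9.87,9.25,49.5,73
2024,8,PFOS,serum,89.1,7.97,150,52.9,70.3,295,68
2024,8,PFDA,serum,202,18.6,256,90.5,121,502,27
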