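case,primary_rmse_mm,primary_duration_s,secondary_rmse_mean_mm,secondary_rmse_sd_mm,secondary_duration_mean_s,n_secondary
1,0.65,42,1.87,0.31,32.41,17
2,1.07,65,1.16,0.34,57.56,9
3,1.25,55,0.96,0.14,34.00,12
4,0.58,54,1.19,0.09,36.60,9
5,1.18,36,0.90,0.32,49.56,9
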