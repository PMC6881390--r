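case,type,angle_preop,angle_plan,angle_postop,width_preop,width_plan,width_postop
1,metopic,99.70,130.03,123.72,78.57,93.28,90.01
2,metopic,99.41,135.14,134.66,73.78,88.41,87.29
3,unicoronal,125.52,144.21,143.17,93.07,97.83,96.15
4,metopic,112.24,130.38,125.00,88.51,95.46,92.16
5,metopic,116.94,139.38,134.46,78.53,84.65,84.60
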