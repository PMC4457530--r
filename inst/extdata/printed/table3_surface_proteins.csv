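gene,mean_normal_pb,mean_pure_b,mean_cll,ratio_cll_pb,ratio_cll_pure_b,p_value,interpretation
CD43,1886.17,17.20,1253.7,0.7,72.9,0.000,increased_vs_normal_b
CD5,1782.16,250.99,4039.1,2.3,16.1,0.000,increased_vs_normal_b
CD200,142.54,3101.54,10131.9,71.1,3.3,0.000,increased_vs_normal_b
FCER2/CD23,226.31,7362.71,15988.5,70.6,2.2,0.000,increased_vs_normal_b
CD79B,181.90,3672.57,4665.0,25.6,1.3,0.421,equal_vs_normal_b
CD19,607.52,17177.12,19164.6,31.5,1.1,0.480,equal_vs_normal_b
CD38,496.21,1108.49,860.8,1.7,0.8,0.760,equal_vs_normal_b
CD79A,3447.71,119505.02,64178.8,18.6,0.5,0.016,decreased_vs_normal_b
CD22,824.90,23927.76,8597.4,10.4,0.4,0.004,decreased_vs_normal_b
MS4A1/CD20,2112.32,66914.33,19628.9,9.3,0.3,0.000,decreased_vs_normal_b
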