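gene,fold_change_cll_vs_pure_b,p_value
BAFF-R/CD268,0.426,0.0018
BANK1,0.224,0.0042
BIRC3,0.484,0.0070
CD22,0.359,0.0036
CD40/TNFRSF5,0.481,0.0000
CD69,0.124,0.0105
CD83,0.086,0.0388
CHL1,0.097,0.0191
CHL1_v4,0.144,0.0000
CXCR4/SDF-1R,0.318,0.0116
EBF1,0.031,0.0210
EBI3,0.172,0.0019
EPB41L2,0.133,0.0011
SERPINA9,0.033,0.0408
IL6,0.001,0.0032
ITGA4/CD49d,0.410,0.0000
JAM3/JAM-C,0.129,0.0001
JUN,0.411,0.0002
LGMN,0.114,0.0249
MMP12,0.019,0.0003
MS4A1/CD20,0.293,0.0001
MYC,0.198,0.0001
NREP,0.280,0.0050
RAGE/MOK,0.451,0.0086
REL,0.335,0.0005
SOX11,0.189,0.0105
TIMP4,0.011,0.0107
ZFP36,0.426,0.0056
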