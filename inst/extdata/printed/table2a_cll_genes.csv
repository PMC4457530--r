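gene,mean_cll,sd_cll,cv
ABCA6,3783.3,1942.9,0.51
ADAM29,482.5,857.1,1.78
AICDA,69.9,143.7,2.06
BIK,414.0,426.0,1.03
BMI1,607.6,202.4,0.33
BUB1B,152.4,118.6,0.78
CD200,10131.9,4443.1,0.44
CD24,9424.4,7446.1,0.79
CD269/BCMA,1857.3,1201.7,0.65
CD27/TNFRSF7,8532.6,3512.4,0.41
CD5,4039.1,1799.7,0.45
CHIT1,243.2,162.8,0.67
CLLU1,5605.3,12595.8,2.25
CNR1/CB1,357.5,533.3,1.49
COL9A2,4955.2,2398.9,0.48
CTLA4,12573.8,11128.3,0.89
CXCR3,1609.2,849.2,0.53
DMD,3625.7,3727.6,1.03
DNMBP,4539.7,2102.5,0.46
FAIM3/Toso,44146.0,20379.2,0.46
FCER2/CD23,15988.5,8133.0,0.51
FGF2,707.3,693.6,0.98
FGFR1,554.3,784.8,1.42
FILIP1L,2284.9,1636.2,0.72
FLT3,406.5,512.4,1.26
FMOD,17401.2,12667.9,0.73
GNRH1,518.1,232.4,0.45
IGFBP4,4858.1,3366.4,0.69
IGHG1to4,13373.7,11186.2,0.84
IGSF3,1129.0,692.7,0.61
IL2RA/IL2R,2205.9,1462.3,0.66
kappa,128933.8,120715.3,0.94
lambda,142654.3,170967.7,1.20
LEF1,7270.0,2323.7,0.32
LILRA4,1799.4,2540.1,1.41
LPL,641.1,681.2,1.06
RAPGEF3,817.9,457.3,0.56
RASGRF1,2960.0,1436.7,0.49
ROR1,2376.8,1107.6,0.47
SELP/CD62,1067.6,708.9,0.66
SEPT10,667.5,1305.7,1.96
SFMBT1,11065.5,3547.0,0.32
TTN,7243.9,3010.2,0.42
WNT3,5240.6,5963.0,1.14
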