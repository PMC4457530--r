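direction,gene,mean_mutated,sd_mutated,mean_unmutated,sd_unmutated,ratio,p_value
up_in_unmutated,SEPT10,10,20,1172,1556,121.0,0.00866
up_in_unmutated,AICDA,1,0,121,174,106.5,0.01562
up_in_unmutated,LDOC1,7,14,368,233,55.4,0.00001
up_in_unmutated,FARP1,3,4,54,83,18.4,0.02412
up_in_unmutated,LPL,91,89,1072,620,11.7,0.00001
up_in_unmutated,CNR1,50,71,582,616,11.6,0.00413
up_in_unmutated,CD38,137,119,1429,2119,10.4,0.02506
up_in_unmutated,DMD,1421,1718,5379,3931,3.8,0.00115
up_in_unmutated,CEACAM1,194,165,590,540,3.0,0.02355
up_in_unmutated,CRY1,501,571,1380,450,2.8,0.00007
up_in_unmutated,ZAP70,1341,563,3482,1209,2.6,0.00001
up_in_unmutated,ITGA4,600,318,1529,1079,2.5,0.00632
up_in_unmutated,TCL1A,15285,14608,38680,18435,2.5,0.00048
up_in_unmutated,CD26,60,63,151,105,2.5,0.00429
up_in_unmutated,CHIT1,135,100,325,157,2.4,0.00045
up_in_unmutated,IGHM,145269,131768,333881,138491,2.3,0.00494
up_in_unmutated,EPB41L2,136,116,305,293,2.2,0.03937
up_in_unmutated,VPREB3,2530,1420,5505,1873,2.2,0.00265
up_in_unmutated,ABCA6,2295,1010,4643,1812,2.0,0.00351
up_in_mutated,CTLA4,18370,13614,8503,6686,2.2,0.03908
up_in_mutated,RARA,3398,3056,1185,586,2.9,0.03850
up_in_mutated,LGMN,114,94,38,38,3.0,0.03412
up_in_mutated,CD150,1665,1117,490,326,3.4,0.00781
up_in_mutated,ADAM29,1061,1091,66,259,16.0,0.00803
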