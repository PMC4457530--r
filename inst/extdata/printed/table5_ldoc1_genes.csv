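direction,gene,mean_ldoc1_neg,mean_ldoc1_pos,ratio,p_value
up_in_ldoc1_pos,LDOC1,1,483,483.4,0.0000
up_in_ldoc1_pos,SEPT10,68,1365,20.2,0.0138
up_in_ldoc1_pos,LPL,154,1331,8.6,0.0000
up_in_ldoc1_pos,CD26/DPP4,45,162,3.6,0.0023
up_in_ldoc1_pos,EPB41L2,132,353,2.7,0.0280
up_in_ldoc1_pos,CXCR6,33,89,2.7,0.0374
up_in_ldoc1_pos,CRY1,551,1404,2.5,0.0001
up_in_ldoc1_neg,CD150,1373,462,3.0,0.0086
up_in_ldoc1_neg,ADAM29,832,2,451.3,0.0096
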