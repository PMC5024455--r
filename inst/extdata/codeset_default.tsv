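probe_id	probe_class	fusion_id	pos_ctrl_concentration
AML1-ETO_junction	endogenous	AML1-ETO	
PML-RARA_junction	endogenous	PML-RARA	
CBFB-MYH11_junction	endogenous	CBFB-MYH11	
TCF3-PBX1_junction	endogenous	TCF3-PBX1	
MLL-AF4_junction	endogenous	MLL-AF4	
BCR-ABL1_junction	endogenous	BCR-ABL1	
ETV6-RUNX1_junction	endogenous	ETV6-RUNX1	
POS_A	positive		128.000
POS_B	positive		32.000
POS_C	positive		8.000
POS_D	positive		2.000
POS_E	positive		0.500
POS_F	positive		0.125
NEG_A	negative		
NEG_B	negative		
NEG_C	negative		
NEG_D	negative		
NEG_E	negative		
NEG_F	negative		
NEG_G	negative		
NEG_H	negative		
TBP	housekeeping		
GUSB	housekeeping		
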