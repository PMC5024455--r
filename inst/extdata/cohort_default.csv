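sample_id,cohort,AML1-ETO,PML-RARA,CBFB-MYH11,TCF3-PBX1,MLL-AF4,BCR-ABL1,ETV6-RUNX1
AML1ETO_01,AML_translocated,true,false,false,false,false,false,false
AML1ETO_02,AML_translocated,true,false,false,false,false,false,false
AML1ETO_03,AML_translocated,true,false,false,false,false,false,false
AML1ETO_04,AML_translocated,true,false,false,false,false,false,false
AML1ETO_05,AML_translocated,true,false,false,false,false,false,false
AML1ETO_06,AML_translocated,true,false,false,false,false,false,false
AML1ETO_07,AML_translocated,true,false,false,false,false,false,false
AML1ETO_08,AML_translocated,true,false,false,false,false,false,false
PMLRARA_01,AML_translocated,false,true,false,false,false,false,false
PMLRARA_02,AML_translocated,false,true,false,false,false,false,false
PMLRARA_03,AML_translocated,false,true,false,false,false,false,false
PMLRARA_04,AML_translocated,false,true,false,false,false,false,false
PMLRARA_05,AML_translocated,false,true,false,false,false,false,false
PMLRARA_06,AML_translocated,false,true,false,false,false,false,false
PMLRARA_07,AML_translocated,false,true,false,false,false,false,false
PMLRARA_08,AML_translocated,false,true,false,false,false,false,false
CBFBMYH11_01,AML_translocated,false,false,true,false,false,false,false
CBFBMYH11_02,AML_translocated,false,false,true,false,false,false,false
CBFBMYH11_03,AML_translocated,false,false,true,false,false,false,false
CBFBMYH11_04,AML_translocated,false,false,true,false,false,false,false
CBFBMYH11_05,AML_translocated,false,false,true,false,false,false,false
CBFBMYH11_06,AML_translocated,false,false,true,false,false,false,false
CBFBMYH11_07,AML_translocated,false,false,true,false,false,false,false
TCF3PBX1_01,ALL,false,false,false,true,false,false,false
TCF3PBX1_02,ALL,false,false,false,true,false,false,false
TCF3PBX1_03,ALL,false,false,false,true,false,false,false
TCF3PBX1_04,ALL,false,false,false,true,false,false,false
MLLAF4_01,ALL,false,false,false,false,true,false,false
MLLAF4_02,ALL,false,false,false,false,true,false,false
MLLAF4_03,ALL,false,false,false,false,true,false,false
MLLAF4_04,ALL,false,false,false,false,true,false,false
MLLAF4_05,ALL,false,false,false,false,true,false,false
MLLAF4_06,ALL,false,false,false,false,true,false,false
MLLAF4_07,ALL,false,false,false,false,true,false,false
BCRABL1_01,ALL,false,false,false,false,false,true,false
BCRABL1_02,ALL,false,false,false,false,false,true,false
BCRABL1_03,ALL,false,false,false,false,false,true,false
BCRABL1_04,ALL,false,false,false,false,false,true,false
BCRABL1_05,ALL,false,false,false,false,false,true,false
BCRABL1_06,ALL,false,false,false,false,false,true,false
BCRABL1_07,ALL,false,false,false,false,false,true,false
ETV6RUNX1_01,ALL,false,false,false,false,false,false,true
ETV6RUNX1_02,ALL,false,false,false,false,false,false,true
ETV6RUNX1_03,ALL,false,false,false,false,false,false,true
ETV6RUNX1_04,ALL,false,false,false,false,false,false,true
ETV6RUNX1_05,ALL,false,false,false,false,false,false,true
ETV6RUNX1_06,ALL,false,false,false,false,false,false,true
ETV6RUNX1_07,ALL,false,false,false,false,false,false,true
ETV6RUNX1_08,ALL,false,false,false,false,false,false,true
NK_01,AML_normal_karyotype,false,false,false,false,false,false,false
NK_02,AML_normal_karyotype,false,false,false,false,false,false,false
NK_03,AML_normal_karyotype,false,false,false,false,false,false,false
NK_04,AML_normal_karyotype,false,false,false,false,false,false,false
NK_05,AML_normal_karyotype,false,false,false,false,false,false,false
NK_06,AML_normal_karyotype,false,false,false,false,false,false,false
NK_07,AML_normal_karyotype,false,false,false,false,false,false,false
NK_08,AML_normal_karyotype,false,false,false,false,false,false,false
NK_09,AML_normal_karyotype,false,false,false,false,false,false,false
NK_10,AML_normal_karyotype,false,false,false,false,false,false,false
NK_11,AML_normal_karyotype,false,false,false,false,false,false,false
NK_12,AML_normal_karyotype,false,false,false,false,false,false,false
NK_13,AML_normal_karyotype,false,false,false,false,false,false,false
NK_14,AML_normal_karyotype,false,false,false,false,false,false,false
NK_15,AML_normal_karyotype,false,false,false,false,false,false,false
NK_16,AML_normal_karyotype,false,false,false,false,false,false,false
NK_17,AML_normal_karyotype,false,false,false,false,false,false,false
NK_18,AML_normal_karyotype,false,false,false,false,false,false,false
NK_19,AML_normal_karyotype,false,false,false,false,false,false,false
CK_01,AML_complex_karyotype,false,false,false,false,false,false,false
CK_02,AML_complex_karyotype,false,false,false,false,false,false,false
CK_03,AML_complex_karyotype,false,false,false,false,false,false,false
CK_04,AML_complex_karyotype,false,false,false,false,false,false,false
CK_05,AML_complex_karyotype,false,false,false,false,false,false,false
CK_06,AML_complex_karyotype,false,false,false,false,false,false,false
CK_07,AML_complex_karyotype,false,false,false,false,false,false,false
CK_08,AML_complex_karyotype,false,false,false,false,false,false,false
CK_09,AML_complex_karyotype,false,false,false,false,false,false,false
CK_10,AML_complex_karyotype,false,false,false,false,false,false,false
CK_11,AML_complex_karyotype,false,false,false,false,false,false,false
CK_12,AML_complex_karyotype,false,false,false,false,false,false,false
CK_13,AML_complex_karyotype,false,false,false,false,false,false,false
CK_14,AML_complex_karyotype,false,false,false,false,false,false,false
CK_15,AML_complex_karyotype,false,false,false,false,false,false,false
CK_16,AML_complex_karyotype,false,false,false,false,false,false,false
CK_17,AML_complex_karyotype,false,false,false,false,false,false,false
CK_18,AML_complex_karyotype,false,false,false,false,false,false,false
CK_19,AML_complex_karyotype,false,false,false,false,false,false,false
CK_20,AML_complex_karyotype,false,false,false,false,false,false,false
CK_21,AML_complex_karyotype,false,false,false,false,false,false,false
NBM_01,normal_marrow,false,false,false,false,false,false,false
NBM_02,normal_marrow,false,false,false,false,false,false,false
NBM_03,normal_marrow,false,false,false,false,false,false,false
NBM_04,normal_marrow,false,false,false,false,false,false,false
NBM_05,normal_marrow,false,false,false,false,false,false,false
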