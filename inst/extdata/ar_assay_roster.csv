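"assay","endpoint_name","role","in_agonist_pathway","in_antagonist_pathway"
"A1","NVS_NR_hAR","receptor-binding",1,1
"A2","NVS_NR_cAR","receptor-binding",1,1
"A3","NVS_NR_rAR","receptor-binding",1,1
"A4","OT_AR_ARSRC1_0480","coregulator-recruitment",1,1
"A5","OT_AR_ARSRC1_0960","coregulator-recruitment",1,1
"A6","UPITT_HCI_U2OS_AR_TIF2_Nucleoli_Agonist","nuclear-translocation-agonist",1,1
"A7","ATG_AR_TRANS_up","RNA-reporter",1,0
"A8","OT_AR_ARELUC_AG_1440","protein-reporter-agonist",1,0
"A9","TOX21_AR_BLA_Agonist_ratio","protein-reporter-agonist",1,0
"A10","TOX21_AR_LUC_MDAKB2_Agonist","protein-reporter-agonist",1,0
"A11","ACEA_AR_agonist_80h","proliferation",1,0
"A12","UPITT_HCI_U2OS_AR_TIF2_Nucleoli_Antagonist","nuclear-translocation-antagonist",0,1
"A13","TOX21_AR_BLA_Antagonist_ratio","protein-reporter-antagonist",0,1
"A14","TOX21_AR_LUC_MDAKB2_Antagonist_0.5nM_R1881","protein-reporter-antagonist",0,1
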