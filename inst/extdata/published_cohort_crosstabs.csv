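variable,grouping,level1,level2,high_level1,high_level2,low_level1,low_level2,printed_p
sex,ccr8_treg,female,male,6,34,2,39,0.15
sex,pct_gzmb,female,male,6,34,2,39,0.15
sex,gzmb_ccr8_ratio,female,male,5,35,3,38,0.48
smoking_status,ccr8_treg,never,current_former,2,38,1,40,0.62
smoking_status,pct_gzmb,never,current_former,2,38,1,40,0.62
smoking_status,gzmb_ccr8_ratio,never,current_former,2,38,1,40,0.62
tumor_laterality,ccr8_treg,left,right,19,21,18,23,0.82
tumor_laterality,pct_gzmb,left,right,18,22,19,22,1.00
tumor_laterality,gzmb_ccr8_ratio,left,right,19,21,18,23,0.82
surgical_procedure,ccr8_treg,wedge_segment,lobe_pneumon,5,35,6,35,1.00
surgical_procedure,pct_gzmb,wedge_segment,lobe_pneumon,4,36,7,34,0.52
surgical_procedure,gzmb_ccr8_ratio,wedge_segment,lobe_pneumon,6,34,5,36,0.76
postoperative_chemo,ccr8_treg,yes,no,6,34,3,38,0.31
postoperative_chemo,pct_gzmb,yes,no,5,35,4,37,0.74
postoperative_chemo,gzmb_ccr8_ratio,yes,no,3,37,6,35,0.48
histological_differentiation,ccr8_treg,well_moderate,poor,38,2,35,6,0.26
histological_differentiation,pct_gzmb,well_moderate,poor,34,6,39,2,0.15
histological_differentiation,gzmb_ccr8_ratio,well_moderate,poor,31,9,30,11,0.80
pT,ccr8_treg,T1_2,T3_4,33,7,31,10,0.59
pT,pct_gzmb,T1_2,T3_4,33,7,31,10,0.59
pN,ccr8_treg,N0,N1_2,26,14,36,5,0.019
pN,pct_gzmb,N0,N1_2,33,7,29,12,0.30
pN,gzmb_ccr8_ratio,N0,N1_2,35,5,27,14,0.035
pStage,ccr8_treg,I,II_III,20,20,26,15,0.27
pStage,pct_gzmb,I,II_III,25,15,21,20,0.37
pStage,gzmb_ccr8_ratio,I,II_III,25,15,21,20,0.37
lymphatic_invasion,ccr8_treg,absent,present,33,7,37,4,0.35
lymphatic_invasion,pct_gzmb,absent,present,38,2,32,9,0.048
lymphatic_invasion,gzmb_ccr8_ratio,absent,present,37,3,33,8,0.19
vascular_invasion,ccr8_treg,absent,present,33,7,38,3,0.19
vascular_invasion,pct_gzmb,absent,present,38,2,33,8,0.088
vascular_invasion,gzmb_ccr8_ratio,absent,present,38,2,33,8,0.088
pleural_invasion,ccr8_treg,absent,present,33,7,37,4,0.35
pleural_invasion,pct_gzmb,absent,present,39,1,31,10,0.0070
pleural_invasion,gzmb_ccr8_ratio,absent,present,38,2,32,9,0.048
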