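column,unit,description
id,,patient identifier
group,,"severity label: low (ICG-R15 < 20%) or high (ICG-R15 >= 20%); derivable from icg_r15"
icg_r15,%,indocyanine green retention at 15 min (reference standard)
age,years,age at imaging
sex,,M or F
height,cm,body height
weight,kg,body weight
hct,%,hematocrit within one week of CT
iwr,%,drawn/derived iodine washout rate
ecv,%,drawn/derived extracellular volume fraction
lv_bsa,mL/m2,liver volume indexed by body surface area
spv_bsa,mL/m2,spleen volume indexed by body surface area
hh15,ratio,blood clearance index (heart counts 15 min / 3 min)
lhl15,ratio,liver receptor index (liver / (liver + heart) counts at 15 min)
enh_pvp,HU,hepatic enhancement during the early portal venous phase
enh_dp,HU,hepatic enhancement during the 3-min delayed phase
lv,mL,liver volume (tumor excluded)
spv,mL,spleen volume
cr,mg/dL,serum creatinine
tbil,mg/dL,total bilirubin
inr,ratio,prothrombin time INR
attn_liver_pre,HU,mean hepatic attenuation (four ROIs) on pre-contrast images
attn_liver_pvp,HU,mean hepatic attenuation during the portal venous phase
attn_liver_dp,HU,mean hepatic attenuation during the delayed phase
attn_aorta_pre,HU,aortic attenuation at the mid-hepatic level pre-contrast
attn_aorta_dp,HU,aortic attenuation at the mid-hepatic level during the delayed phase
aortic_enh_dp,HU,aortic delayed-phase enhancement
heart_c3,counts,heart ROI counts at 3 min post injection
heart_c15,counts,heart ROI counts at 15 min post injection
liver_c3,counts,liver ROI counts at 3 min post injection
liver_c15,counts,liver ROI counts at 15 min post injection
reader2_attn_liver_pre,HU,second reader re-measurement of attn_liver_pre (optional)
reader2_attn_liver_pvp,HU,second reader re-measurement of attn_liver_pvp (optional)
reader2_attn_liver_dp,HU,second reader re-measurement of attn_liver_dp (optional)
reader2_attn_aorta_pre,HU,second reader re-measurement of attn_aorta_pre (optional)
reader2_attn_aorta_dp,HU,second reader re-measurement of attn_aorta_dp (optional)
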