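item,unit,price_usd_2021,category
acetylsalicylic_acid_81mg_tab,10x10,1.303,drug
adrenaline_0.1pct_1ml_amp,each,1.074,drug
amiodarone_100mg_tab,10x3,9.337,drug
amlodipine_10mg_tab,10x10,3.142,drug
amlodipine_5mg_tab,10x10,2.243,drug
atenolol_50mg_tab,10x10,1.749,drug
atorvastatin_20mg_tab,10x10,5.831,drug
atorvastatin_40mg_tab,10x3,4.195,drug
candesartan_8mg_tab,14x2,4.548,drug
captopril_12.5mg_tab,10x10,1.000,drug
captopril_25mg_tab,10x10,0.802,drug
captopril_hct_50_25mg_tab,10x10,1.708,drug
digoxin_0.25mg_tab,10x10,6.025,drug
enalapril_10mg_tab,10x10,1.835,drug
enalapril_5mg_tab,10x10,1.905,drug
enalapril_2.5mg_tab,10x10,0.595,drug
enalapril_hct_10_25mg_tab,10x10,2.331,drug
glibenclamide_5mg_tab,10x10,1.165,drug
glyceryl_trinitrate_0.4mg_tab,100,14.518,drug
hydralazine_20mg_ml_amp,5,6.079,drug
hydrochlorothiazide_25mg_tab,25x4,1.432,drug
insulin_isophane_biphasic_10ml,each,2.539,drug
insulin_isophane_human_10ml,each,2.988,drug
insulin_soluble_human_10ml,each,3.165,drug
lovastatin_20mg_tab,10x10,2.521,drug
metformin_500mg_tab,10,0.828,drug
methyldopa_250mg_tab,100x10,1.542,drug
metoprolol_50mg_tab,10x10,2.814,drug
nifedipine_20mg_tab,10x10,1.749,drug
propranolol_40mg_tab,10x10,2.013,drug
spironolactone_25mg_tab,10x10,2.440,drug
valsartan_hct_80_12.5mg_tab,7x2,1.146,drug
complete_blood_count,test,1.72,lab
fasting_random_blood_sugar,test,0.46,lab
lipid_profile,test,3.68,lab
echocardiography,test,2.76,lab
electrocardiogram,test,8.05,lab
ct_scan,test,27.59,lab
renal_function_test,test,1.84,lab
chest_xray,test,16.69,lab
urine_analysis,test,0.34,lab
liver_function_test,test,2.76,lab
thyroid_function_test,test,9.93,lab
bed_day_primary_hospital,day,1.21,facility
bed_day_secondary_hospital,day,1.26,facility
bed_day_tertiary_hospital,day,1.63,facility
visit_primary_hospital,visit,0.43,facility
visit_secondary_hospital,visit,0.49,facility
visit_tertiary_hospital,visit,0.51,facility
visit_health_center,visit,0.53,facility
pci_intervention,procedure,1448.28,facility
inpatient_mi,episode,1040.00,facility
inpatient_stroke,episode,940.00,facility
outpatient_ihd_annual,year,45.00,facility
outpatient_stroke_annual,year,67.00,facility
salary_physician,month,485.06,staff
salary_acute_care_nurse,month,171.72,staff
salary_pharmacy_personnel,month,184.99,staff
salary_laboratory_technician,month,148.51,staff
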