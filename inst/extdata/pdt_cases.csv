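ps,case,admin_dose_mg_kg,wavelength_nm,drug_light_interval_min,lobe,surface_exposure_J_cm2,conc_ug_g,conc_spread_ug_g,conc_uM_printed,necrosis_depth_mm,pf_ratio_mmHg,dynamic_compliance_mL_cmH2O,static_compliance_mL_cmH2O,gross_or_histology_injury
ALA,1,60,630,210,upper,12,0.96,0.71,57.2,1.7,97,6,6,TRUE
ALA,1,60,630,210,lower,6,0.96,0.71,57.2,1.0,97,6,6,TRUE
ALA,2,30,630,210,upper,12,0.062,0.05,28.6,1.4,440,9,9,TRUE
ALA,2,30,630,210,lower,6,0.062,0.05,28.6,0.7,440,9,9,TRUE
ALA,3,30,630,210,both,12,0.052,0.06,28.6,1.1,248,9,9,TRUE
ALA,4,15,630,210,both,12,0.032,0.23,14.3,0,456,13,12,FALSE
Chlorin,1,1,660,60,upper,14.4,NA,NA,NA,0,593,13,14,FALSE
Chlorin,1,1,660,60,lower,7.2,NA,NA,NA,0,593,13,14,FALSE
Chlorin,2,1,665,15,spot,240,NA,NA,NA,0,459,13,14,FALSE
Chlorin,3,1,665,0,spot,285,2.2,1.76,503,11,331,11,11,TRUE
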