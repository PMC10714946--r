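age_band,weight_class,dose_lo_mg,dose_hi_mg
children_10_12,normal,2.5,3.125
children_10_12,obese,3.125,3.75
early_adol_12_15,normal,3.125,3.75
early_adol_12_15,obese,3.75,5
adol_15_18,normal,3.75,5
adol_15_18,obese,NA,NA
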