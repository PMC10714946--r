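molecular_weight: 4813.5
log_p: -6.8
solubility: 1.0
fu: 0.01
ka: 0.0996
bioavailability: 0.81
cl_spec_peptidase: 0.35
peptidase_conc: 1.0
gfr_fraction: 1.0
f_urine: 0.66
renal_cl_param: 0.12
cl_pept_factor: 0.001
kp_scale: 0.13
partition_method: composition
fixed_kp: 1.0
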