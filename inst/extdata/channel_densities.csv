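"section","kind","gna_S_cm2","na_shift_mV","gkdr_S_cm2","gka_S_cm2_min","gka_S_cm2_max","gcah_S_cm2_max","gcal_S_cm2_max","gkca_S_cm2"
"axon","axon",0.6,0,0.01,0,0,0,0,0
"basal","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"basal_a","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"basal_a_a","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"basal_a_b","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"basal_b","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"basal_b_a","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"basal_b_b","basal",0.009,5,0.01,0.029,0.029,0.00015,0,0.00025
"oblique","oblique",0.009,5,0.01,0.0526,0.1214,0.00015,0,0.00025
"soma","soma",0.009,0,0.01,0.029,0.029,3e-04,0,5e-04
"trunk_dist","trunk",0.009,5,0.01,0.0528,0.1444,0.00015,0,0.00025
"trunk_prox","trunk",0.009,5,0.01,0.0296,0.0516,0.00015,0,0.00025
"tuft_a","tuft",0.009,5,0.01,0.145,0.145,0.00045,0.005,0.00025
"tuft_a_a","tuft",0.009,5,0.01,0.145,0.145,0.00015,0,0.00025
"tuft_a_b","tuft",0.009,5,0.01,0.145,0.145,0.00015,0,0.00025
"tuft_b","tuft",0.009,5,0.01,0.145,0.145,0.00045,0.005,0.00025
"tuft_b_a","tuft",0.009,5,0.01,0.145,0.145,0.00015,0,0.00025
"tuft_b_b","tuft",0.009,5,0.01,0.145,0.145,0.00015,0,0.00025
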