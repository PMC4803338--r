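"parameter","value"
"cm_uF_cm2",0.75
"ra_ohm_cm",150
"rm_ohm_cm2",40000
"el_mV",-70
"e_na_mV",60
"e_k_mV",-80
"e_ca_mV",140
"celsius",30
"dt_ms",0.1
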