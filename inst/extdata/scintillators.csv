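name,class,density_g_cm3,peak_emission_nm,light_yield_ph_per_MeV,decay_ns,rise_ns
BGO,dense,7.13,480,8500,317,1.0
LGSO,dense,7.15,430,28000,40,1.0
GAGG,dense,6.63,530,42000,90,1.0
EJ200,fast,1.02,425,10000,2.1,0.5
EJ228,fast,1.02,391,10200,1.4,0.5
EJ232,fast,1.02,370,8400,1.6,0.5
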