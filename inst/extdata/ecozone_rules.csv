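ecozone,rule,source_ecozone,storage_const_t_ha,seq_const_t_ha_yr
Pacific maritime,pool,,,
Montane cordillera,pool,,,
Boreal plains,constant,,40.0,3.0
Subhumid prairies,pool,,,
Semiarid prairies,copy,Subhumid prairies,,
Boreal shield west,constant,,40.0,3.0
Mixedwood plains,pool,,,
Boreal shield east,constant,,40.0,3.0
Atlantic maritime,pool,,,
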