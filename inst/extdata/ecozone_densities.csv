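ecozone,storage_density_t_ha,seq_rate_t_ha_yr,source,comment
Pacific maritime,97.4,6.9,PROXY_CITY,Derived from the Seattle assessment
Montane cordillera,22.6,1.4,POOLED,Kelowna
Boreal plains,40.0,3.0,FOREST_MODEL,Derived from managed boreal forest models
Subhumid prairies,54.7,2.9,POOLED,Calgary and Edmonton
Semiarid prairies,54.7,2.9,PROXY_CITY,Derived from Subhumid Prairies
Boreal shield west,40.0,3.0,FOREST_MODEL,Derived from managed boreal forest models
Mixedwood plains,57.8,2.4,POOLED,12 Ontario cities
Boreal shield east,40.0,3.0,FOREST_MODEL,Derived from managed boreal forest models
Atlantic maritime,61.6,3.4,POOLED,Halifax
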