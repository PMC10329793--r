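ru_id,name,ru_area_km2,urban_area_km2,canopy_area_km2,canopy_cover_pct,ecozone
1,BC Pacific maritime,200716,1991,766,38.5,Pacific maritime
2,BC Montane cordillera,428955,526,136,25.8,Montane cordillera
3,AB Boreal plains,367539,111,32,29.0,Boreal plains
4,AB Semiarid prairies,71203,262,17,6.6,Semiarid prairies
5,AB Subhumid prairies,80577,1691,197,11.6,Subhumid prairies
6,SK Boreal plains,164464,70,22,32.1,Boreal plains
7,SK Semiarid prairies,154361,340,40,11.7,Semiarid prairies
8,MB Subhumid prairies,64079,539,85,15.8,Subhumid prairies
9,ON Boreal shield west,335151,183,87,47.7,Boreal shield west
10,ON Mixedwood plains,82439,5317,1193,22.4,Mixedwood plains
11,ON Boreal shield east,241097,574,232,40.3,Boreal shield east
12,QC Boreal shield east,600491,142,47,32.8,Boreal shield east
13,QC Mixedwood plains,27707,3240,961,29.7,Mixedwood plains
14,QC Atlantic maritime,67077,217,85,39.0,Atlantic maritime
15,NB Atlantic maritime,71389,512,252,49.2,Atlantic maritime
16,NS Atlantic maritime,53247,337,168,50.0,Atlantic maritime
17,PE Atlantic maritime,5654,70,16,22.3,Atlantic maritime
18,NL Boreal shield east,104740,190,83,43.8,Boreal shield east
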