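name,ru_id,external,assessment_area_ha,n_plots,carbon_storage_t,carbon_storage_se_t,seq_gross_t_yr,seq_gross_se_t_yr,canopy_area_override_ha,note
Halifax,16,FALSE,69270,190,2134697,156789,118483,8228,,
Ajax,10,FALSE,6743,198,105641,18065,3547,471,,
Aurora,10,FALSE,4943,205,102981,12824,4050,418,,
Bolton,10,FALSE,1677,46,12682,4341,757,185,,typographically ambiguous source row; parse cross-checked against the published pooled Mixedwood density (57.8) and the published city-density minimum (33.8)
Brampton,10,FALSE,26945,196,174736,30078,7732,1130,,
Caledon,10,FALSE,478,37,13689,3468,590,128,,typographically ambiguous source row; parse cross-checked against the published pooled Mixedwood density (57.8) and the published city-density maximum (127.9)
London,10,FALSE,23591,383,359763,42669,12451,1145,,
Markham,10,FALSE,21269,213,229886,42226,9229,1413,,
Mississauga,10,FALSE,28801,205,202870,40786,10002,1493,,
Oakville,10,FALSE,9893,367,49724,4937,4177,390,,
Pickering,10,FALSE,4718,219,104191,13733,4242,428,,
Richmond Hill,10,FALSE,10201,208,165699,26595,7241,876,,
Toronto,10,FALSE,63727,407,1107645,99010,46741,3302,,
Kelowna,2,FALSE,21723,150,126911,19245,7713,1300,,
Calgary,5,FALSE,55032,196,183595,39072,10108,1679,,
Edmonton,5,FALSE,69985,307,615774,91284,31848,4055,,
Seattle,1,TRUE,54324,223,535261,,37817,,5498.913,external surrogate city; canopy area from its own satellite estimate was never published and is back-calculated from the published RU-1 storage total (535261 x 76600 / 7456200)
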