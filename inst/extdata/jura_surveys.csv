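survey,period,n_camera_traps,mean_trap_days,n_occasions,n_detections,n_individuals,n_female,n_unknown,n_male
2011_Doubs,January-April,48,63,15,22,4,1,1,2
2011_Jura,February-April,66,59,15,42,9,1,7,1
2012_Jura_Doubs,February-April,148,69,17,130,21,2,14,5
2013_Doubs,February-April,44,63,14,25,6,1,4,1
2013_Ain_Jura,February-April,142,58,13,117,19,2,13,4
2014_Ain,February-April,118,59,13,158,23,4,16,3
2015_Ain,February-May,30,99,21,38,10,2,8,0
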