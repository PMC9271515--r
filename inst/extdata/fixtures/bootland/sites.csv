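id,lat,lon,year,n_trials,country
bl_n1,45,9,2019,12,bootland
bl_n2,45,12,2019,8,bootland
bl_c1,42,13,2019,4,bootland
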