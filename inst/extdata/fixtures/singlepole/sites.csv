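id,lat,lon,year,n_trials,country
singlepole_2019_s01,43,23,2019,9,singlepole
singlepole_2019_s02,43,22.5,2019,1,singlepole
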