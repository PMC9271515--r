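id,lat,lon,year,n_trials,country
uniform_2019_s01,50,4,2019,4,uniform
uniform_2019_s02,50.5,4,2019,4,uniform
uniform_2019_s03,51,4,2019,4,uniform
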