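id,lat,lon,year,n_trials,country
tl_site_w,0,-2.5,2019,5,twolobe
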