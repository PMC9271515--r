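id,lat,lon,population,country
tl_01,0,-3,50,twolobe
tl_02,0,-2.5,4e+05,twolobe
tl_03,0,-2,50,twolobe
tl_04,0,-1.5,50,twolobe
tl_05,0,-1,50,twolobe
tl_06,0,-0.5,50,twolobe
tl_07,0,0,50,twolobe
tl_08,0,0.5,50,twolobe
tl_09,0,1,50,twolobe
tl_10,0,1.5,50,twolobe
tl_11,0,2,50,twolobe
tl_12,0,2.5,4e+05,twolobe
tl_13,0,3,50,twolobe
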