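id,lat,lon,population,country
bl_01,44,8,1800000,bootland
bl_02,45,8,1800000,bootland
bl_03,46,8,1800000,bootland
bl_04,44,9,1800000,bootland
bl_05,45,9,1800000,bootland
bl_06,46,9,1800000,bootland
bl_07,44,10,1800000,bootland
bl_08,45,10,1800000,bootland
bl_09,46,10,1800000,bootland
bl_10,44,11,1800000,bootland
bl_11,45,11,1800000,bootland
bl_12,46,11,1800000,bootland
bl_13,44,12,1800000,bootland
bl_14,45,12,1800000,bootland
bl_15,46,12,1800000,bootland
bl_16,44,13,1800000,bootland
bl_17,45,13,1800000,bootland
bl_18,46,13,1800000,bootland
bl_19,41,12,6e+05,bootland
bl_20,42,12,6e+05,bootland
bl_21,43,12,6e+05,bootland
bl_22,41,13,6e+05,bootland
bl_23,42,13,6e+05,bootland
bl_24,43,13,6e+05,bootland
bl_25,41,14,6e+05,bootland
bl_26,42,14,6e+05,bootland
bl_27,43,14,6e+05,bootland
bl_28,41,15,6e+05,bootland
bl_29,42,15,6e+05,bootland
bl_30,43,15,6e+05,bootland
bl_31,38,15,6e+05,bootland
bl_32,39,15,6e+05,bootland
bl_33,40,15,6e+05,bootland
bl_34,38,16,6e+05,bootland
bl_35,39,16,6e+05,bootland
bl_36,40,16,6e+05,bootland
bl_37,38,17,6e+05,bootland
bl_38,39,17,6e+05,bootland
bl_39,40,17,6e+05,bootland
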