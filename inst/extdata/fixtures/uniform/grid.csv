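id,lat,lon,population,country
uniform_0001,50,4,55556,uniform
uniform_0002,50.5,4,55556,uniform
uniform_0003,51,4,55556,uniform
uniform_0004,51.5,4,55556,uniform
uniform_0005,52,4,55556,uniform
uniform_0006,52.5,4,55556,uniform
uniform_0007,50,4.5,55556,uniform
uniform_0008,50.5,4.5,55556,uniform
uniform_0009,51,4.5,55556,uniform
uniform_0010,51.5,4.5,55556,uniform
uniform_0011,52,4.5,55556,uniform
uniform_0012,52.5,4.5,55556,uniform
uniform_0013,50,5,55556,uniform
uniform_0014,50.5,5,55556,uniform
uniform_0015,51,5,55556,uniform
uniform_0016,51.5,5,55556,uniform
uniform_0017,52,5,55556,uniform
uniform_0018,52.5,5,55556,uniform
uniform_0019,50,5.5,55556,uniform
uniform_0020,50.5,5.5,55556,uniform
uniform_0021,51,5.5,55555,uniform
uniform_0022,51.5,5.5,55555,uniform
uniform_0023,52,5.5,55555,uniform
uniform_0024,52.5,5.5,55555,uniform
uniform_0025,50,6,55555,uniform
uniform_0026,50.5,6,55555,uniform
uniform_0027,51,6,55555,uniform
uniform_0028,51.5,6,55555,uniform
uniform_0029,52,6,55555,uniform
uniform_0030,52.5,6,55555,uniform
uniform_0031,50,6.5,55555,uniform
uniform_0032,50.5,6.5,55555,uniform
uniform_0033,51,6.5,55555,uniform
uniform_0034,51.5,6.5,55555,uniform
uniform_0035,52,6.5,55555,uniform
uniform_0036,52.5,6.5,55555,uniform
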