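id,lat,lon,population,country
singlepole_0001,40,20,12245,singlepole
singlepole_0002,40.5,20,12245,singlepole
singlepole_0003,41,20,12245,singlepole
singlepole_0004,41.5,20,12245,singlepole
singlepole_0005,42,20,12245,singlepole
singlepole_0006,42.5,20,12245,singlepole
singlepole_0007,43,20,12245,singlepole
singlepole_0008,40,20.5,12245,singlepole
singlepole_0009,40.5,20.5,12245,singlepole
singlepole_0010,41,20.5,12245,singlepole
singlepole_0011,41.5,20.5,12245,singlepole
singlepole_0012,42,20.5,12245,singlepole
singlepole_0013,42.5,20.5,12247,singlepole
singlepole_0014,43,20.5,12248,singlepole
singlepole_0015,40,21,12245,singlepole
singlepole_0016,40.5,21,12245,singlepole
singlepole_0017,41,21,12245,singlepole
singlepole_0018,41.5,21,12248,singlepole
singlepole_0019,42,21,12280,singlepole
singlepole_0020,42.5,21,12404,singlepole
singlepole_0021,43,21,12507,singlepole
singlepole_0022,40,21.5,12245,singlepole
singlepole_0023,40.5,21.5,12245,singlepole
singlepole_0024,41,21.5,12248,singlepole
singlepole_0025,41.5,21.5,12341,singlepole
singlepole_0026,42,21.5,13418,singlepole
singlepole_0027,42.5,21.5,17505,singlepole
singlepole_0028,43,21.5,20918,singlepole
singlepole_0029,40,22,12245,singlepole
singlepole_0030,40.5,22,12245,singlepole
singlepole_0031,41,22,12280,singlepole
singlepole_0032,41.5,22,13418,singlepole
singlepole_0033,42,22,26544,singlepole
singlepole_0034,42.5,22,76330,singlepole
singlepole_0035,43,22,117903,singlepole
singlepole_0036,40,22.5,12245,singlepole
singlepole_0037,40.5,22.5,12247,singlepole
singlepole_0038,41,22.5,12404,singlepole
singlepole_0039,41.5,22.5,17505,singlepole
singlepole_0040,42,22.5,76330,singlepole
singlepole_0041,42.5,22.5,299453,singlepole
singlepole_0042,43,22.5,485772,singlepole
singlepole_0043,40,23,12245,singlepole
singlepole_0044,40.5,23,12248,singlepole
singlepole_0045,41,23,12507,singlepole
singlepole_0046,41.5,23,20918,singlepole
singlepole_0047,42,23,117903,singlepole
singlepole_0048,42.5,23,485771,singlepole
singlepole_0049,43,23,792958,singlepole
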