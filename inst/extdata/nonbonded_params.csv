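resid,name,charge,sigma,epsilon
SER,N,-0.500,3.250,0.170
SER,H,0.300,0.000,0.000
SER,CA,0.140,3.500,0.066
SER,HA,0.060,2.500,0.030
SER,C,0.500,3.750,0.105
SER,O,-0.500,2.960,0.210
GDP,C8,0.200,3.550,0.070
GDP,H8,0.100,2.420,0.030
GDP,N9,-0.300,3.250,0.170
GDP,C1',0.100,3.500,0.066
GDP,H1',0.060,2.500,0.030
GDP,C2',0.100,3.500,0.066
GDP,H2',0.060,2.500,0.030
GDP,O2',-0.400,3.120,0.170
GDP,C5',0.050,3.500,0.066
GDP,H5',0.030,2.500,0.030
GDP,H5'',0.030,2.500,0.030
GDP,O5',-0.400,2.900,0.140
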