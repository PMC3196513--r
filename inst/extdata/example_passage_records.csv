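flask_index,day,n0_cells,final_od600,growth_rate_per_h,condition,mutagen
1,1,85000,0.71,0.22,glycerol,false
2,2,85000,0.70,0.25,glycerol,false
3,3,85000,0.72,0.31,glycerol,false
4,4,85000,0.69,0.45,glycerol,false
5,5,85000,0.71,0.55,glycerol,false
6,6,85000,0.73,0.60,glycerol,false
7,7,85000,0.70,0.63,glycerol,false
8,8,85000,0.71,0.64,glycerol,false
9,9,85000,0.72,0.64,glycerol,false
10,10,85000,0.70,0.63,glycerol,false
11,11,85000,0.71,0.64,glycerol,false
12,12,85000,0.69,0.64,glycerol,false
13,13,85000,0.71,0.64,glycerol,false
14,14,85000,0.72,0.64,glycerol,false
15,15,85000,0.70,0.64,glycerol,false
16,16,85000,0.71,0.63,glycerol,false
17,17,85000,0.70,0.64,glycerol,false
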