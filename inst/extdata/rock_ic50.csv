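compound_id,kinase,measure,value,unit,dose_uM,flags
1,ROCK1,IC50,44,uM,,extrapolated
1,ROCK1,percent_inhibition,43,percent,10,extrapolated
1,ROCK2,percent_inhibition,27,percent,10,
2,ROCK1,IC50,1.74,uM,,
2,ROCK2,IC50,2.90,uM,,
3,ROCK1,percent_inhibition,23,percent,10,extrapolated
3,ROCK2,IC50,2.61,uM,,
12,ROCK1,IC50,0.0075,uM,,
12,ROCK2,IC50,0.0141,uM,,
13,ROCK1,IC50,3.39,uM,,
13,ROCK2,IC50,3.98,uM,,
14,ROCK1,IC50,0.106,uM,,
14,ROCK2,IC50,0.036,uM,,
17,ROCK1,IC50,0.005,uM,,
17,ROCK2,IC50,0.003,uM,,
18,ROCK1,IC50,0.003,uM,,
18,ROCK2,IC50,0.001,uM,,
21,ROCK1,IC50,1.143,uM,,
21,ROCK2,IC50,0.051,uM,,
22,ROCK1,IC50,0.394,uM,,
22,ROCK2,IC50,0.232,uM,,
23,ROCK1,IC50,0.870,uM,,
23,ROCK2,IC50,0.353,uM,,
24,ROCK1,IC50,1.254,uM,,
24,ROCK2,IC50,1.077,uM,,
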