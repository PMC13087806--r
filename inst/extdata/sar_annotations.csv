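compound_id,hinge_scaffold,linker_ch2,terminal_group
12,7-azaindole,2,indole
13,pyridine,2,indole
14,indazole,2,indole
15,5-7-azaindole,2,indole
16,pyrazole,2,indole
17,7-azaindole,1,indole
18,indazole,1,indole
19,5-7-azaindole,1,indole
20,pyrazole,1,indole
21,indazole,0,trimethoxyphenyl
22,7-azaindole,0,trimethoxyphenyl
23,indazole,1,trimethoxyphenyl
24,7-azaindole,1,trimethoxyphenyl
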