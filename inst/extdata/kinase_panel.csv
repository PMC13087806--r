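compound_id,kinase,percent_inhibition,dose_uM
18,IKKb/IKBKB,4.0,0.5
18,JAK1,5.3,0.5
18,MLCK/MYLK,15.4,0.5
18,PKAcb,94.0,0.5
18,PKCa,6.5,0.5
18,PKG1a,98.9,0.5
21,IKKb/IKBKB,2.7,0.5
21,JAK1,4.2,0.5
21,MLCK/MYLK,8.1,0.5
21,PKAcb,4.4,0.5
21,PKCa,2.3,0.5
21,PKG1a,32.9,0.5
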