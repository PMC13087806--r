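compound_id,assay,pe,fa_percent
fasudil,GIT,3.575,74
21,GIT,5.562,88
fasudil,BBB,1.364,
21,BBB,0.537,
12,BBB,2.453,
17,BBB,2.614,
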