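id,class,name,smiles,formula,acid_id,aldehyde_id,adduct,hrms_calc_mz,note
25,acid,2-(1H-indol-3-yl)acetic acid,OC(=O)Cc1c[nH]c2ccccc12,C10H9NO2,,,,,
26,acid,3-(1H-indol-3-yl)propanoic acid,OC(=O)CCc1c[nH]c2ccccc12,C11H11NO2,,,,,
29,acid,"3,4,5-trimethoxybenzoic acid",OC(=O)c1cc(OC)c(OC)c(OC)c1,C10H12O5,,,,,
30,acid,"2-(3,4,5-trimethoxyphenyl)acetic acid",OC(=O)Cc1cc(OC)c(OC)c(OC)c1,C11H14O5,,,,,
6,aldehyde,isoquinoline-5-carbaldehyde,O=Cc1cccc2cnccc12,C10H7NO,,,,,
7,aldehyde,quinoline-4-carbaldehyde,O=Cc1ccnc2ccccc12,C10H7NO,,,,,
8,aldehyde,4-(pyridin-4-yl)benzaldehyde,O=Cc1ccc(-c2ccncc2)cc1,C12H9NO,,,,,
9,aldehyde,isonicotinaldehyde,O=Cc1ccncc1,C6H5NO,,,,,
10,aldehyde,"1H-pyrrolo[2,3-b]pyridine-5-carbaldehyde",O=Cc1cnc2[nH]ccc2c1,C8H6N2O,,,,,
11,aldehyde,"1H-pyrrolo[2,3-b]pyridine-3-carbaldehyde",O=Cc1c[nH]c2ncccc12,C8H6N2O,,,,,
IND5,aldehyde,1H-indazole-5-carbaldehyde,O=Cc1ccc2[nH]ncc2c1,C8H6N2O,,,,,
PP5,aldehyde,"7H-pyrrolo[2,3-d]pyrimidine-5-carbaldehyde",O=Cc1c[nH]c2ncncc12,C7H5N3O,,,,,
PZ4,aldehyde,1H-pyrazole-4-carbaldehyde,O=Cc1c[nH]nc1,C4H4N2O,,,,,
27,hydrazide,2-(1H-indol-3-yl)acetohydrazide,NNC(=O)Cc1c[nH]c2ccccc12,C10H11N3O,25,,,,
28,hydrazide,3-(1H-indol-3-yl)propanehydrazide,NNC(=O)CCc1c[nH]c2ccccc12,C11H13N3O,26,,,,
31,hydrazide,"3,4,5-trimethoxybenzohydrazide",NNC(=O)c1cc(OC)c(OC)c(OC)c1,C10H14N2O4,29,,,,
32,hydrazide,"2-(3,4,5-trimethoxyphenyl)acetohydrazide",NNC(=O)Cc1cc(OC)c(OC)c(OC)c1,C11H16N2O4,30,,,,
12,product,"(E)-N'-((1H-pyrrolo[2,3-b]pyridin-3-yl)methylene)-3-(1H-indol-3-yl)propanehydrazide",O=C(CCc1c[nH]c2ccccc12)NN=Cc1c[nH]c2ncccc12,C19H17N5O,26,11,[M+H]+,332.15059,
13,product,(E)-3-(1H-indol-3-yl)-N'-(pyridin-4-ylmethylene)propanehydrazide,O=C(CCc1c[nH]c2ccccc12)NN=Cc1ccncc1,C17H16N4O,26,9,[M+H]+,293.13969,
14,product,(E)-N'-((1H-indazol-5-yl)methylene)-3-(1H-indol-3-yl)propanehydrazide,O=C(CCc1c[nH]c2ccccc12)NN=Cc1ccc2[nH]ncc2c1,C19H17N5O,26,IND5,[M-H]-,330.13604,
15,product,"(E)-N'-((7H-pyrrolo[2,3-d]pyrimidin-5-yl)methylene)-3-(1H-indol-3-yl)propanehydrazide",O=C(CCc1c[nH]c2ccccc12)NN=Cc1c[nH]c2ncncc12,C18H16N6O,26,PP5,[M+Na]+,355.12778,
16,product,(E)-N'-((1H-pyrazol-4-yl)methylene)-3-(1H-indol-3-yl)propanehydrazide,O=C(CCc1c[nH]c2ccccc12)NN=Cc1c[nH]nc1,C15H15N5O,26,PZ4,[M+Cl]-,316.09796,printed calculated value inconsistent with the formula by ~0.9 mDa
17,product,"(E)-N'-((1H-pyrrolo[2,3-b]pyridin-3-yl)methylene)-2-(1H-indol-3-yl)acetohydrazide",O=C(Cc1c[nH]c2ccccc12)NN=Cc1c[nH]c2ncccc12,C18H15N5O,25,11,[M-H]-,316.12039,
18,product,(E)-N'-((1H-indazol-5-yl)methylene)-2-(1H-indol-3-yl)acetohydrazide,O=C(Cc1c[nH]c2ccccc12)NN=Cc1ccc2[nH]ncc2c1,C18H15N5O,25,IND5,[M+H]+,318.13494,
19,product,"(E)-N'-((7H-pyrrolo[2,3-d]pyrimidin-5-yl)methylene)-2-(1H-indol-3-yl)acetohydrazide",O=C(Cc1c[nH]c2ccccc12)NN=Cc1c[nH]c2ncncc12,C17H14N6O,25,PP5,[M+H]+,319.13019,printed calculated value one 5th-decimal unit above the bundled mass-table arithmetic
20,product,(E)-N'-((1H-pyrazol-4-yl)methylene)-2-(1H-indol-3-yl)acetohydrazide,O=C(Cc1c[nH]c2ccccc12)NN=Cc1c[nH]nc1,C14H13N5O,25,PZ4,[M+H]+,268.11929,
21,product,"(E)-N'-((1H-indazol-5-yl)methylene)-3,4,5-trimethoxybenzohydrazide",O=C(c1cc(OC)c(OC)c(OC)c1)NN=Cc1ccc2[nH]ncc2c1,C18H18N4O4,29,IND5,[M+H]+,355.14008,
22,product,"(E)-N'-((1H-pyrrolo[2,3-b]pyridin-3-yl)methylene)-3,4,5-trimethoxybenzohydrazide",O=C(c1cc(OC)c(OC)c(OC)c1)NN=Cc1c[nH]c2ncccc12,C18H18N4O4,29,11,[M+H]+,355.14008,
23,product,"(E)-N'-((1H-indazol-5-yl)methylene)-2-(3,4,5-trimethoxyphenyl)acetohydrazide",O=C(Cc1cc(OC)c(OC)c(OC)c1)NN=Cc1ccc2[nH]ncc2c1,C19H20N4O4,30,IND5,[M+H]+,369.15573,
24,product,"(E)-N'-((1H-pyrrolo[2,3-b]pyridin-3-yl)methylene)-2-(3,4,5-trimethoxyphenyl)acetohydrazide",O=C(Cc1cc(OC)c(OC)c(OC)c1)NN=Cc1c[nH]c2ncccc12,C19H20N4O4,30,11,[M+H]+,369.15573,
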