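element,monoisotopic_mass
H,1.00782503207
B,11.0093054
C,12.0
N,14.0030740048
O,15.9949146196
F,18.99840322
Na,22.9897692809
Mg,23.9850417
Si,27.9769265325
P,30.97376163
S,31.97207100
Cl,34.96885268
K,38.96370668
Ca,39.96259098
Fe,55.9349375
Zn,63.9291422
Br,78.9183371
I,126.904473
Li,7.01600455
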