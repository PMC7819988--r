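symbol	mass
e	0.00054857990907
H	1.00782503223
C	12.0
N	14.00307400443
O	15.99491461957
P	30.97376199842
S	31.9720711744
Na	22.9897692820
K	38.9637064864
F	18.99840316273
Cl	34.968852682
Br	78.9183376
I	126.9044719
Si	27.97692653465
Mg	23.985041697
Ca	39.962590863
Fe	55.934935537
Se	79.9165218
Li	7.0160034366
B	11.00930536
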