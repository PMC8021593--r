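burden_row,SE,SZ,HEP,NL/SL
>=90,9,0,21,3
50-89,0,3,21,15
10-49,0,3,20,56
1-9,0,0,5,18
0,0,2,20,157
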