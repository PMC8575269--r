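unit,kind,S,G,E
A,bioregion,117,50,88
A1,bioprovince,60,41,26
A2,bioprovince,72,31,46
B,bioregion,126,52,82
B1,bioprovince,43,24,9
B2,bioprovince,101,43,50
B3,bioprovince,20,15,2
C,bioregion,74,42,40
C1,bioprovince,67,37,33
C2,bioprovince,12,10,4
D,bioregion,78,47,34
D1,bioprovince,33,25,12
D2,bioprovince,55,37,18
E,bioregion,85,51,45
E1,bioprovince,28,21,5
E2,bioprovince,28,22,5
E3,bioprovince,55,38,17
E4,bioprovince,19,13,3
Galapagos,independent,10,9,2
Hawaii,independent,11,9,2
AmsterdamStPaul,independent,7,7,2
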