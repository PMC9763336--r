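amino_acid,hydrophobicity,polarity,charge,aromatic_or_aliphatic
A,Y,N,N,N
C,Y,Y,N,N
D,N,Y,negative,N
E,N,Y,negative,N
F,Y,N,N,aromatic
G,Y,N,N,N
H,Y,Y,positive,aromatic
I,Y,N,N,aliphatic
K,Y,Y,positive,N
L,Y,N,N,aliphatic
M,Y,N,N,N
N,N,Y,N,N
P,N,N,N,N
Q,N,Y,N,N
R,N,Y,positive,N
S,N,Y,N,N
T,Y,Y,N,N
V,Y,N,N,aliphatic
W,Y,Y,N,aromatic
Y,Y,Y,N,aromatic
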