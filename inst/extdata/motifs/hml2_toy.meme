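MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF COM1 COM1
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000

MOTIF COM2 COM2
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000

MOTIF HS1 HS1
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000

MOTIF HS2 HS2
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000

MOTIF HS3 HS3
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000

MOTIF A1 A1
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000

MOTIF A2 A2
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000

MOTIF A3 A3
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000

MOTIF B1 B1
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.050000 0.850000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000

MOTIF B2 B2
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.850000 0.050000 0.050000

MOTIF B3 B3
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000
0.050000 0.850000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.850000 0.050000 0.050000 0.050000
0.050000 0.850000 0.050000 0.050000
0.050000 0.050000 0.050000 0.850000
0.050000 0.050000 0.850000 0.050000
0.050000 0.050000 0.850000 0.050000

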