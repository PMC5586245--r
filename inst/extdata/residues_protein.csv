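# Amino-acid residue (in-chain, i.e. amino acid minus water) elemental
# composition in the neutral protonation state, count of exchangeable
# (labile) hydrogens (backbone amide plus side-chain OH/NH/SH; proline has
# no amide H), and residue volume in cubic Angstrom (Zamyatnin (1972),
# Prog. Biophys. Mol. Biol. 24, 107-123).
letter,C,H,N,O,S,labile_h,volume_A3
A,3,5,1,1,0,1,88.6
R,6,12,4,1,0,5,173.4
N,4,6,2,2,0,3,114.1
D,4,5,1,3,0,2,111.1
C,3,5,1,1,1,2,108.5
Q,5,8,2,2,0,3,143.8
E,5,7,1,3,0,2,138.4
G,2,3,1,1,0,1,60.1
H,6,7,3,1,0,2,153.2
I,6,11,1,1,0,1,166.7
L,6,11,1,1,0,1,166.7
K,6,12,2,1,0,3,168.6
M,5,9,1,1,1,1,162.9
F,9,9,1,1,0,1,189.9
P,5,7,1,1,0,0,112.7
S,3,5,1,2,0,2,89.0
T,4,7,1,2,0,2,116.1
W,11,10,2,1,0,2,227.8
Y,9,9,1,2,0,2,193.6
V,5,9,1,1,0,1,140.0
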