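# Atomic constants used for composition-based scattering calculations.
# mass: average atomic weight (IUPAC 2021, Da); electrons: atomic number;
# b_coh_fm: bound coherent neutron scattering length (Sears, Neutron News 3
# (1992) 26-37), femtometres. "D" is deuterium (2H).
element,mass,electrons,b_coh_fm
H,1.00794,1,-3.7390
D,2.01422,1,6.6710
C,12.011,6,6.6460
N,14.007,7,9.3600
O,15.999,8,5.8030
P,30.974,15,5.1300
S,32.060,16,2.8470
Na,22.990,11,3.6300
Mg,24.305,12,5.3750
Cl,35.450,17,9.5770
K,39.098,19,3.6700
Ca,40.078,20,4.7000
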