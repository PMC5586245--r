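# Built-in solvent components: chemical formula and approximate partial
# molar volume in solution (cm^3/mol; Millero (1971) Chem. Rev. 71, 147 for
# simple electrolytes, estimates from crystal/liquid densities for buffers).
# Users may supply their own formula/volume for chemicals not listed.
name,formula,molar_volume_cm3
NaCl,NaCl,16.6
KCl,KCl,26.8
CaCl2,CaCl2,17.8
MgCl2,MgCl2,14.5
NaN3,NaN3,29.0
MOPS,C7H15NO4S,162.0
HEPES,C8H18N2O4S,191.0
Tris,C4H11NO3,116.0
TCEP,C9H15O6P,186.0
DTT,C4H10O2S2,118.0
glycerol,C3H8O3,70.8
urea,CH4N2O,44.2
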