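# Nucleotide residue (in-chain nucleoside 5'-monophosphate minus water,
# neutral phosphodiester form) elemental composition, exchangeable-hydrogen
# counts (base amino/imino protons; RNA adds the 2'-OH), and nominal residue
# volumes chosen to reproduce a partial specific volume of 0.57 cm^3/g,
# the canonical value for polynucleotides (Durchschlag (1986), in Thermodynamic
# Data for Biochemistry and Biotechnology).
kind,letter,C,H,N,O,P,labile_h,volume_A3
dna,A,10,12,5,5,1,2,296.4
dna,C,9,12,3,6,1,2,273.8
dna,G,10,12,5,6,1,3,311.6
dna,T,10,13,2,7,1,1,287.9
rna,A,10,12,5,6,1,3,311.6
rna,C,9,12,3,7,1,3,288.9
rna,G,10,12,5,7,1,4,326.7
rna,U,9,11,2,8,1,2,289.9
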