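# Structural alert SMARTS used for the ALERTS desirability of QED:
# undesirable / reactive functionality commonly excluded from screening sets.
# Patterns restricted to the SMARTS dialect OpenBabel parses.
[N+](=O)[O-]
C(=O)Cl
C(=O)Br
S(=O)(=O)Cl
N=C=O
N=C=S
C=C=O
[SH]
[CH]=O
O=C1CCC(=O)N1Cl
[N;!$(N=O)]=[N]
N#N
[P;!$(P(=O)([O,N])([O,N])[O,N])]
C1OC1
C1NC1
[Cl,Br,I]C(=O)
[Cl,Br,I]CC(=O)
C(=O)OC(=O)
[C;!$(C(=O))]=[N;!R]
S=C
[Se,Te,As,Hg,Pb,Cd]
[Si]
O=C(O)C(=O)O
C=CC=CC=C
[O,S][O,S]
[N+][O-]
[C-]
[c;$(c1ccccc1[N+](=O)[O-])]
I
[Mg,Fe,Cu,Zn,Mn,Ni,Co,Cr]
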