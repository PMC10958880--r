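# Reference compound set used to derive the fragment frequency table for
# the synthetic accessibility score. Common drugs, drug-like molecules and
# small fragments; chosen to cover routine medicinal-chemistry environments
# (alkyl chains, common heterocycles, amides, esters, sulfonamides, halogens).
CC(=O)Oc1ccccc1C(=O)O
CC(C)Cc1ccc(cc1)C(C)C(=O)O
Cn1cnc2c1c(=O)n(C)c(=O)n2C
CC(=O)Nc1ccc(O)cc1
Clc1ccccc1C(=O)Nc1ccccc1
CCOC(=O)c1ccccc1
CCN(CC)CC(=O)Nc1c(C)cccc1C
OCC(O)CO
NCCc1ccc(O)c(O)c1
CC(N)Cc1ccccc1
OC(=O)CCC(=O)O
NC(=O)c1ccccc1
O=C(O)c1ccccc1O
Nc1ccc(cc1)S(=O)(=O)N
CC(C)NCC(O)COc1ccccc1
c1ccc2[nH]ccc2c1
c1ccc2ncccc2c1
c1ccncc1
c1ccoc1
c1ccsc1
c1cnc[nH]1
c1cn[nH]c1
c1cncnc1
c1ccc(nc1)N
Cc1ccccc1
CCc1ccccc1
COc1ccccc1
Oc1ccccc1
Nc1ccccc1
Clc1ccccc1
Fc1ccccc1
Brc1ccccc1
CC(=O)c1ccccc1
O=Cc1ccccc1
N#Cc1ccccc1
CS(=O)(=O)c1ccccc1
O=S(=O)(N)c1ccccc1
CCOC(=O)C
CC(=O)OC
CC(=O)NC
CCNC(=O)CC
CCOCC
CCSCC
CCCCCC
CCCCCCCC
CC(C)CC(C)C
CCO
CCN
CCC(=O)O
CC(C)O
CC(C)=O
CCC#N
C1CCCCC1
C1CCCC1
C1CCNCC1
C1CCOCC1
C1CCNC1
C1CCOC1
C1CN(CCN1)C
O=C1CCCCC1
OC1CCCCC1
NC1CCCCC1
C1CC1
C1CCC1
CN1CCCC1
CN1CCCCC1
O=C1NCCC1
O=C1NC(=O)NC(=O)C1
CC12CCC(CC1)CC2
c1ccc(cc1)c1ccccc1
c1ccc(cc1)Cc1ccccc1
c1ccc(cc1)Oc1ccccc1
c1ccc(cc1)Nc1ccccc1
O=C(Nc1ccccc1)c1ccccc1
O=C(Cc1ccccc1)NC
COc1ccc(cc1)CCN
CN(C)CCc1ccccc1
OCc1ccccc1
NCc1ccccc1
ClCc1ccccc1
CC(=O)N1CCCCC1
O=C(O)C1CCCCC1
c1ccc2c(c1)cccc2
c1ccc2c(c1)ncccc2=O
Cc1ncc([nH]1)C
Cc1nccs1
Cc1occc1
Cc1ccc(o1)C=O
Cc1ccc(s1)C
c1cc2cccnc2[nH]1
c1ccc2c(c1)oc(n2)N
c1ccc2c(c1)sc(n2)N
c1ccc2c(c1)nc([nH]2)N
CC(C)(C)OC(=O)NC
CC(C)(C)c1ccccc1
CC(C)Oc1ccccc1
FC(F)(F)c1ccccc1
COc1ccc2c(c1)[nH]cc2
CCOc1ccccc1OC
CN1CCN(CC1)c1ccccc1
O=C(N1CCOCC1)c1ccccc1
C1COCCN1
C1CNCCN1
CC(=O)N1CCOCC1
CCS(=O)(=O)NC
CNC(=O)Oc1ccccc1
CCOC(=O)N1CCCC1
Nc1ncnc2c1ncn2C
OCC1OC(O)C(O)C(O)C1O
CC(O)C(O)CO
OCCOCCO
NCCN
NCCO
OCCO
CNC
CN(C)C
CCNCC
CC(C)N
O=C(N)N
NC(=N)N
CSC
CS(C)=O
OS(=O)(=O)O
COP(=O)(OC)OC
CCOP(=O)(OCC)OCC
Cc1cc(C)cc(C)c1
Cc1ccc(C)cc1
Clc1ccc(Cl)cc1
Oc1ccc(Cl)cc1
Nc1ccc(F)cc1
COc1ccc(N)cc1
Cc1cccc(C)c1N
CC(=O)Nc1ccccc1O
O=C(O)c1cccnc1
O=C(O)c1ccncc1
Nc1cccnc1
Oc1cccnc1
Cc1ccncc1
c1ccc(cc1)S(=O)(=O)Nc1ccccc1
O=C(NCc1ccccc1)C1CC1
CC1(C)CCCC1
CC1CCCCC1N
OC(c1ccccc1)c1ccccc1
N#CC1CCCCC1
OCCN1CCCCC1
CCCN(CCC)CCC
CC(C)(C)N
CC(C)(O)C
CC(Cl)C
CC(Br)C
CCI
CC=C
CC=CC
CC#C
C=CC(=O)NC
CC(=O)C=C
COC(=O)C=C
c1ccc(cc1)C=CC(=O)O
CC(=O)CC(=O)C
CC(=O)CC(=O)OC
O=C1OC(=O)c2ccccc12
O=C1NC(=O)c2ccccc12
CN1C(=O)CC(=O)N(C)C1=O
c1ccc(cc1)n1cccn1
Cn1ccnc1
Cn1cccn1
CCn1cc(cn1)C
c1ccc(cc1)C1CCNCC1
O=C(O)CN
NC(Cc1ccccc1)C(=O)O
NC(CO)C(=O)O
NC(CS)C(=O)O
CC(NC(=O)C)C(=O)O
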