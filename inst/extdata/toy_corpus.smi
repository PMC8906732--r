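# toy SMILES corpus (H/C/N/O), generated combinatorially from small fragments
Oc1cncnc1
OCC=CC#N
C=CC=CC=CCC(C)C
N#CC=CC=C(C)C
Cc1cnc[nH]1
C=Cc1ccccc1
C=C
Cc1ccc2c(c1)cccc2
Nc1cnco1
Nc1ccncc1
CCOC=C(C)C
CC(=C)COC=O
COc1cncnc1
c1ccc2c(c1)nccc2
C=CC=Cc1cncnc1
CC=Cc1cocn1
Nc1c[nH]cc1
CCOCCC
CCNNC=O
CC=CC#N
COc1cocc1
C#N
OCC=CC=C
C=CC=Cc1cnco1
NCCC=CCO
C=CC=Cc1cocc1
Oc1cnco1
NCCC=CC#N
C=Cc1cncnc1
C=CC=CC=C
COc1c[nH]cc1
C=CC=CC=CC=CC#N
CCNC=C
CCCCNC
CCCCC=C
Oc1ccncc1
Oc1cnc[nH]1
C=CC=CC#N
CC=Cc1cnco1
OCC=CC=CC=C
N(C=O)C=CC#N
OCc1c[nH]cc1
C=CC=Cc1ccncc1
CC=C
O=COC=CC=C
CC=Cc1c[nH]cc1
CC=CCC=CCO
NCCC(C)C
OCc1ccncc1
CN
NCCC=CC=CC=C
Nc1cnc[nH]1
CNCN
C=Cc1ccncc1
CCNCN
CCOC=CC=C
C=CC#N
CNOC=O
CNCC
CCOOC=O
Cc1cocn1
Nc1ccccc1
CCCCNC=O
CC=CCC=CC=C
CC=Cc1ccncc1
C=CC=CC=CCC(=C)C
CCCCC=CC
CCCCOC
Nc1cocc1
COCC
OCc1cnc[nH]1
O=CCC=CC
CCCCCCC
OC=O
CC=Cc1cocc1
CCOCN
C=CC=Cc1ccccc1
CO
CCCCC#N
OCCC=CCO
Cc1cnco1
C=CC=CC=CC=C
CCNCC=CC
COc1cnco1
CCCCC=CC=CC=C
CCOCC#N
OCc1ccc2c(c1)cccn2
CCC
CC(=C)CC=O
CCCO
O=CNC=CC=C
Oc1ccc2c(c1)cccn2
C=O
COC=O
CC(=C)CCO
c1ncco1
c1ccccc1
CCCC
Cc1ccc2c(c1)cccn2
COc1ccncc1
CC=Cc1ccccc1
COc1ccc2c(c1)cccc2
CCCCC(C)C
CCCOC=O
CCCCCC#N
C=CC=C(C)C
Oc1cocn1
CC=CC
CCC=C
Nc1ccc2c(c1)cccc2
C=Cc1cnco1
CC(CCC(C)C)C
CCCCCC
Cc1c[nH]cc1
COC#N
CC
CCCCN
C=Cc1cocn1
N#CCC=CC#N
CNCC(C)C
Oc1cocc1
CCO
Nc1ccc2c(c1)cccn2
C=Cc1cnc[nH]1
Cc1cncnc1
CC=Cc1cncnc1
CCNOCC=C
CC(C)C
C=CC=Cc1cnc[nH]1
C=CC=CCC(C)C
OCc1ccc2c(c1)cccc2
CCCC=CC=C
COc1cnc[nH]1
C=CC=C
OCC=CNC=O
C=CC=CC=CC=O
COC=C
CCCCC
OCc1ccccc1
Cc1ccncc1
Oc1c[nH]cc1
c1cccnc1
CCNCO
CC#N
CC=CCCCO
CCCCCO
C=CC=Cc1c[nH]cc1
COC=C(C)C
C=CCOCC=CC
C=COC=O
OCc1cncnc1
C=Cc1ccc2c(c1)cccn2
C=CC=CC=CC=CC=C
Oc1ccc2c(c1)cccc2
Cc1ccccc1
NCC=CC=CC=C
OCc1cnco1
OCC=C
Nc1cncnc1
CC=Cc1cnc[nH]1
CC=Cc1ccc2c(c1)cccn2
C=CCC=CC
c1ccncn1
C=CC=Cc1cocn1
COc1ccc2c(c1)cccn2
CCNCCC
CCCC#N
OCc1cocc1
O=COCC(C)C
c1ncc[nH]1
NC=O
Oc1ccccc1
CCCC=C(C)C
C=Cc1c[nH]cc1
c1ccc2c(c1)cccc2
Nc1cocn1
CC=Cc1ccc2c(c1)cccc2
C=CC=Cc1ccc2c(c1)cccc2
C=CC=Cc1ccc2c(c1)cccn2
CCNC=O
c1ccco1
CC=C(C)C
Cc1cocc1
COc1cocn1
OCC=COC=O
CNCC#N
CCC=C(C)C
C=Cc1cocc1
COc1ccccc1
O=c1ccc2c(o1)cccc2
c1ccc[nH]1
CC(CC#N)C
CCCCOCC=C
C=Cc1ccc2c(c1)cccc2
CCCCO
CCN
CC(=C)C
OCc1cocn1
O=CNCC(C)C
O=CNC=CC=CC=C
CCCCCCO
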