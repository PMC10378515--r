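COL5A1
COL5A2
COL3A1
COL1A1
COL6A1
COL6A2
CHST14
FBN1
FLG
VWF
F2
LIFR
NLRP3
STAT1
T1CAM1
TNFRSF13B
ADAMTS2
C1R
IF1H1
NFKB2
POLG
NDUFA11
NDUFS3
IKBKAP
WNT10A
SLC6A2
FOXP2
RBM20
ZNF469
PIK3R1
TMPRSS6
SLC12A3
UMOD
PKD1
OPA1
TYMP
SCN5A
SCN10A
SCN11A
LPIN1
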