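ACE2
TMPRSS2
CCR1
CCR5
CXCR6
IFNAR1
IFNAR2
STAT2
ICAM1
IFITM3
IFNA1
IRF9
F2
LIFR
NLRP3
STAT1
TICAM1
TNFRSF13B
ADAMTS13
C3
IFR3
NFKB1
POLD4
NDUFAF7
IKBKG
WNT3
SLC6A20
FOXP4
RBM15
ZNF275
PIK3C3
ATP6V1A
FURIN
TEAD3
DPP7
DPP9
DDR1
SFTPD
ACE
AGT
AGTR1
RAB7A
APOE
NPC1
AR
TLR7
TLR3
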