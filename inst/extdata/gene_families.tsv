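root	member
C_complement	C1R
C_complement	C3
POL	POLG
POL	POLD4
IKBK	IKBKAP
IKBK	IKBKG
NDUF	NDUFA11
NDUF	NDUFAF7
WNT	WNT10A
WNT	WNT3
SLC6	SLC6A2
SLC6	SLC6A20
RBM	RBM20
RBM	RBM15
ZNF	ZNF469
ZNF	ZNF275
PIK3	PIK3R1
PIK3	PIK3C3
IRF	IFIH1
IRF	IRF3
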