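id	synonyms
MTH1	MTH1	HTR1	DGT1
HXT3	HXT3
CDC13	CDC13	EST4
CDC25	CDC25	CTN1
MDM2	MDM2	HDM2
TP53	P53	TP53
CDKN1A	CDKN1A	P21	WAF1	CIP1
CHZ1	CHZ1
HTB1	H2B	HTB1	HTB2
SIR3	SIR3	SIR3P	CMT1
SIR4	SIR4	SIR4P	UTH2
CLN1	CLN1
NPL4	NPL4	HRD4
UFD1	UFD1
CDC48	CDC48
CDC14	CDC14	OAF3
CDC28	CDC28	CDK1	SRM5
ISW2	ISW2
INO80	INO80
PIS1	PIS1
LACZ	LACZ
ATG1	ATG1	APG1	AUT3
GPD1	GPD1	GPDI	DAR1	HOR1
HSP12	HSP12
HSP104	HSP104
IME1	IME1
GAL1	GAL1
GAL4	GAL4
GAL80	GAL80
ACT1	ACT1
CLN2	CLN2
CLB5	CLB5
SWI4	SWI4
SWI6	SWI6
MBP1	MBP1
FUS3	FUS3
STE12	STE12
HOG1	HOG1
MSN2	MSN2
MSN4	MSN4
RAP1	RAP1
ABF1	ABF1
TUP1	TUP1
SSN6	SSN6	CYC8
SNF2	SNF2
GCN4	GCN4
HAP4	HAP4
PHO4	PHO4
PHO85	PHO85
SIC1	SIC1
FAR1	FAR1
RAD53	RAD53
MEC1	MEC1
DUN1	DUN1
YAP1	YAP1
ROX1	ROX1
HMO1	HMO1
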