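BKS_01	BKS
BKS_02	BKS
BKS_03	BKS
DUR_01	DUR
DUR_02	DUR
DUR_03	DUR
DUR_04	DUR
JNP_01	JNP
JNP_02	JNP
JNP_03	JNP
JNP_04	JNP
JNP_05	JNP
KNP_01	KNP
KNP_02	KNP
KNP_03	KNP
KWB_01	KWB
KWB_02	KWB
KWB_03	KWB
LDR_01	LDR
LDR_02	LDR
LDR_03	LDR
YKS_01	YKS
YKS_02	YKS
YKS_03	YKS
YKS_04	YKS
YMP_01	YMP
YMP_02	YMP
YMP_03	YMP
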