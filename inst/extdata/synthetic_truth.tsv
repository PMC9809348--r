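key	target_breed	object_freq	background_freq
11:682278:T:A	JNP	1	0
8:367461:G:C	JNP	1	0
13:215269:G:C	JNP	1	0
7:482640:A:G	JNP	1	0
5:519532:C:T	KNP	1	0
14:959547:T:A	KNP	1	0
4:583270:C:G	KNP	1	0
6:936200:T:C	KNP	1	0
2:78718:C:A	KWB	1	0
2:947985:C:T	KWB	1	0
8:11860:A:C	KWB	1	0
15:41801:C:T	KWB	1	0
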