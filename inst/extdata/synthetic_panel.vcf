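##fileformat=VCFv4.2
##source=breedmark
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	BKS_01	BKS_02	BKS_03	DUR_01	DUR_02	DUR_03	DUR_04	JNP_01	JNP_02	JNP_03	JNP_04	JNP_05	KNP_01	KNP_02	KNP_03	KWB_01	KWB_02	KWB_03	LDR_01	LDR_02	LDR_03	YKS_01	YKS_02	YKS_03	YKS_04	YMP_01	YMP_02	YMP_03
1	123625	rs41903628	C	T	.	.	.	GT	./.	0/1	0/1	1/1	1/1	0/1	1/1	0/1	0/1	1/1	1/1	1/1	./.	1/1	0/0	1/1	0/1	1/1	1/1	1/1	1/1	0/1	1/1	0/0	1/1	0/1	1/1	1/1
2	78718	rs71925401	C	A	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
2	202048	rs66560684	A	T	.	.	.	GT	1/1	1/1	0/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	0/1	0/0	1/1	0/0	1/1	1/1	1/1	1/1	./.	1/1	0/1	1/1	1/1	1/1
2	320837	.	C	T	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/1	./.	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0
2	502153	rs65296630	G	A	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	0/0	0/0	0/0	0/0	0/0	0/0
2	658368	.	C	G	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
2	685213	rs16373824	A	T	.	.	.	GT	1/1	1/1	0/1	./.	1/1	0/1	1/1	1/1	0/1	0/1	1/1	1/1	0/1	1/1	1/1	0/1	0/1	0/1	1/1	1/1	0/1	1/1	1/1	0/0	1/1	1/1	0/1	0/0
2	947985	rs71166857	C	T	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	./.	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
3	842653	.	A	T	.	.	.	GT	1/1	1/1	1/1	1/1	./.	0/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	0/1	0/1	0/1	1/1	1/1	1/1	1/1	0/1	0/1	1/1	1/1	1/1	0/1	0/1	1/1
3	942339	.	G	A	.	.	.	GT	0/1	0/1	0/1	0/1	1/1	1/1	0/1	1/1	1/1	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	1/1	0/1	0/0	1/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0
4	428724	.	T	C	.	.	.	GT	0/1	0/1	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
4	583270	rs30710352	C	G	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	0/0	0/0
4	958969	rs59631541	C	T	.	.	.	GT	1/1	0/1	0/1	1/1	1/1	1/1	0/1	0/1	0/1	0/1	1/1	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/1	1/1	0/0	0/1	0/0	0/1	0/1	1/1	0/1	1/1
5	258969	rs10789464	A	T	.	.	.	GT	1/1	1/1	1/1	0/1	0/0	0/1	1/1	1/1	0/1	1/1	1/1	0/0	1/1	0/1	0/1	0/1	1/1	1/1	1/1	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1	0/1
5	519532	rs29533554	C	T	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
5	980559	rs69682425	C	G	.	.	.	GT	1/1	1/1	1/1	0/0	0/1	0/0	0/0	0/1	1/1	0/1	0/1	1/1	./.	1/1	1/1	0/1	1/1	0/0	0/1	0/0	0/1	1/1	1/1	0/1	1/1	0/0	0/1	0/1
6	243933	.	G	C	.	.	.	GT	./.	0/0	0/0	0/0	0/0	0/1	0/0	./.	1/1	0/1	0/0	0/0	0/0	0/1	1/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0
6	341805	.	T	C	.	.	.	GT	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0
6	677734	.	T	G	.	.	.	GT	1/1	1/1	1/1	0/1	1/1	0/0	1/1	0/1	0/0	0/0	1/1	0/1	0/0	1/1	0/1	0/1	0/0	0/0	0/1	0/1	0/1	1/1	1/1	1/1	0/1	0/1	0/1	0/1
6	936200	.	T	C	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
7	352113	rs9752376	T	A	.	.	.	GT	1/1	1/1	1/1	0/0	1/1	0/0	0/0	1/1	1/1	0/1	1/1	0/1	1/1	0/0	./.	1/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	0/1	1/1	1/1	1/1
7	482640	rs81725459	A	G	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
7	775347	.	C	A	.	.	.	GT	0/0	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/0	0/0	1/1	1/1	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/1
8	11860	rs61036553	A	C	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	./.	0/0	0/0	./.	0/0	0/0	./.	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
8	38691	rs36354078	T	C	.	.	.	GT	0/1	0/1	0/0	0/1	0/1	0/1	0/1	0/1	1/1	1/1	0/1	0/1	1/1	1/1	1/1	0/1	0/1	0/1	1/1	0/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1
8	367461	rs32978530	G	C	.	.	.	GT	0/0	./.	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	0/0
8	398593	.	A	G	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	1/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/0
9	21096	rs43069675	C	A	.	.	.	GT	1/1	0/0	0/1	1/1	1/1	1/1	1/1	0/1	0/1	0/0	0/0	0/0	0/1	0/1	1/1	1/1	0/0	0/1	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/0
9	205909	.	T	C	.	.	.	GT	0/1	0/0	0/0	0/0	0/0	0/1	0/1	1/1	1/1	1/1	0/1	1/1	0/1	0/0	0/0	0/0	0/1	0/0	./.	0/0	0/0	0/1	1/1	1/1	1/1	0/0	0/1	./.
9	253391	rs84471049	C	G	.	.	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	1/1	0/1	0/1	0/1	0/1	./.	1/1	0/1	0/0
9	265525	.	G	C	.	.	.	GT	0/0	0/0	0/0	1/1	1/1	0/1	1/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	1/1	0/0	0/1	0/1	0/0	./.	0/1	1/1	0/1	1/1	1/1	0/1	0/1	0/1
9	837473	.	G	C	.	.	.	GT	0/0	1/1	./.	0/0	0/0	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	1/1	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/1	1/1	0/0	0/0	0/0
10	181790	.	T	C	.	.	.	GT	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	0/1	0/0	0/0	1/1	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/0
10	266131	.	A	G	.	.	.	GT	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	0/0	1/1	1/1	1/1	0/1	0/1	1/1	0/0	0/1	1/1	1/1	1/1	1/1
10	598444	rs94236404	A	T	.	.	.	GT	0/1	0/0	1/1	0/1	0/1	0/1	1/1	0/1	0/0	0/0	0/0	0/0	0/1	1/1	0/1	0/1	./.	1/1	1/1	1/1	1/1	0/0	./.	0/0	0/1	0/0	0/0	0/1
11	682278	rs19249903	T	A	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
11	816737	.	T	A	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/1	0/0	0/1
11	828530	.	T	G	.	.	.	GT	0/0	0/0	0/0	0/1	1/1	0/1	0/1	1/1	0/1	0/0	./.	0/1	0/0	0/1	1/1	0/0	0/1	1/1	0/1	0/0	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/0
12	276	.	T	G	.	.	.	GT	./.	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/0	0/0	./.	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0
12	202706	.	T	C	.	.	.	GT	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	1/1	0/1	1/1	0/0	0/1	1/1	0/0	1/1	0/1	0/0	0/0	0/1	0/0	1/1	0/0	0/0
12	284194	rs91570172	T	A	.	.	.	GT	0/1	1/1	1/1	0/1	0/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	1/1	1/1	./.	0/0	0/1	0/0	0/0	0/0	./.	0/1	1/1	1/1	1/1
12	623132	rs31760887	G	A	.	.	.	GT	1/1	0/0	1/1	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/1	1/1	1/1	0/1	1/1	1/1	0/1	0/1	0/0	1/1	0/1	1/1	0/1	1/1	0/1	0/1	1/1	1/1
13	215269	.	G	C	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
14	529185	.	C	T	.	.	.	GT	0/1	0/0	1/1	1/1	1/1	1/1	0/1	1/1	1/1	0/1	1/1	0/0	0/1	0/0	1/1	0/1	0/1	1/1	0/0	0/1	0/1	0/1	1/1	0/1	0/1	1/1	1/1	1/1
14	959547	rs54103540	T	A	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
15	41801	.	C	T	.	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	1/1	1/1	1/1	0/0	0/0	0/0	0/0	./.	0/0	0/0	0/0	0/0	0/0
15	462425	.	C	A	.	.	.	GT	0/1	0/1	1/1	1/1	0/0	0/0	1/1	1/1	1/1	0/0	0/0	1/1	0/1	0/1	1/1	1/1	0/0	0/0	1/1	0/1	0/1	0/1	1/1	0/0	0/1	1/1	0/1	0/1
17	113964	.	C	A	.	.	.	GT	1/1	0/0	0/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	1/1	1/1	1/1
17	166165	.	A	G	.	.	.	GT	0/0	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/1	1/1	1/1	0/0	1/1	0/0	0/0	0/0	0/1	0/1
17	789612	rs62209795	A	G	.	.	.	GT	1/1	1/1	1/1	0/0	0/1	1/1	1/1	1/1	1/1	1/1	1/1	./.	1/1	1/1	1/1	1/1	0/1	1/1	1/1	1/1	./.	1/1	1/1	1/1	1/1	1/1	1/1	1/1
18	526051	rs70695486	T	G	.	.	.	GT	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/1	./.	0/1	0/1	0/1
18	766584	rs22294918	T	G	.	.	.	GT	0/0	0/0	1/1	1/1	./.	1/1	1/1	1/1	1/1	1/1	0/0	1/1	0/1	0/0	0/1	1/1	0/1	1/1	./.	1/1	0/1	0/0	0/1	0/0	0/0	0/0	1/1	1/1
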