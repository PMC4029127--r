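mirna	mature_seq	length	seedlings	flag_leaves	developing_seeds
tae-miR1120b	UUCUUAUAUUGUGGGACAGAG	21	26	131	56
tae-miR1120c	UAAUAUAAGAACGUUUUUGAC	21	0	24	0
tae-miR1122b	AGACUUAUAUGUAGGAACGGA	21	0	0	10
tae-miR1122c	UCUAAUAUUAUGGGACGGAGG	21	4	8	4
tae-miR1127b	ACAAGUAUUUCUGGACGGAGG	21	0	0	17
tae-miR1130b	UCUUAUAUUAUGGGACGGAGG	21	0	10	0
tae-miR1137b	UCCGUUCCAGAAUAGAUGACC	21	9	13	28
tae-miR167c	UGAAGCUGCCAGCAUGAUCUGC	22	67	173	88
tae-miR1847	ACCUGCAGUUGGGCCAAUGAC	21	47	106	20
tae-miR2275	UUUGGUUUCCUCCAAUAUCUCG	22	0	0	12
tae-miR396	AACUGUGAACUCGCGGGGAUG	21	6	11	35
tae-miR397	UCACCGGCGCUGCACACAAUG	21	2	92	5
tae-miR5048	UUUGCAGGUUUUAGGUCUAAGU	22	1142	1274	0
tae-miR5049	AAUAUGGAUCGGAGGGAGUAC	21	1	13	1
tae-miR5062	UGAACCUUAGGGAACAGCCGCAU	23	510	1509	2932
tae-miR5175	UUCCAAAUUACUCGUCGUGGU	21	0	129	34
tae-miR5384	UGAGCGCGCCGCCGUCGAAUG	21	0	12	0
tae-miR6197	UCUGUAAACAAAUGUAGGACG	21	29	71	131
tae-miR7757	AUAAAACCUUCAGCUAUCCAUC	22	67	83	78
tae-miR9652-3P	AAGCUUAAUGAGAACAUGUG	20	0	14	1
tae-miR9652-5P	CCUGUUUGUCAUUAAGUUUCUU	22	2	0	10
tae-miR9653	UUUGAGACUUUGGCCAUGGCC	21	0	0	15
tae-miR9654a	UUCUGAAAGGCUUGAAGCGAAU	22	0	0	135
tae-miR9654b	UUCCGAAAGGCUUGAAGCGAAU	22	1	3	34
tae-miR9655	CAAGGGAAGGAAGUAGCCAAC	21	15	1	1047
tae-miR9656	CUUCGAGACUCUGAACAGCGG	21	0	0	18
tae-miR9657a	UGUGCUUCCUCGUCGAACGGU	21	0	0	46
tae-miR9657b	UUCGUCGGAGAAGCAUGUUGC	21	0	0	60
tae-miR9657c	CGUGCUUCCUCGUCGAACGGU	21	16	39	29
tae-miR9658	AUCGUUCUGGGUGAAUAGGCC	21	7	10	299
tae-miR9659	UCCAAUGGUUGUUCACGGCAUC	22	0	0	248
tae-miR9660	UUGCGAGCAACGGAUGAAUC	20	0	0	21
tae-miR9661	UGAAGUAGAGCAGGGACCUCA	21	2	1	27
tae-miR9662a	UUGAACAUCCCAGAGCCACCG	21	402	488	898
tae-miR9662b	UGAACAUCCCAGAGCCACCGG	21	0	488	821
tae-miR9663	AAGCGUAGUCGAACGAAUCUG	21	1634	5562	10441
tae-miR9664	UUGCAGUCCUCGAUGUCGUAG	21	243	305	1122
tae-miR9665	GCUAGCAGUGUAAACUCAAAUCA	23	0	0	9
tae-miR9666a	CGGUAGGGCUGUAUGAUGGCGA	22	46	47	1519
tae-miR9666b	CGGUUGGGCUGUAUGAUGGCGA	22	8913	29	477
tae-miR9666c	GCCAUCAUACGUCCAACCGUG	21	10	0	0
tae-miR9667	AAAUAUGGCAAACAAUGAAUG	21	0	0	27
tae-miR9668	CCAAUGACAAGUAUUUUCGGA	21	0	10	9
tae-miR9669	UACUGUGGGCACUUAUUUGAC	21	9	0	0
tae-miR9670	AGGUGGAAUACUUGAAGAAGA	21	140	218	409
tae-miR9671	UGACUUUACACAACUGUCCGGC	22	6	13	0
tae-miR9672	CCACGACUGUCAUUAAGCAUC	21	92	366	36
tae-miR9673	UAAGAAGCAAAUAGCACAUG	20	4	14	11
tae-miR9674a	GCAUCAUCCAUCCUACCAUUC	21	143	346	337
tae-miR9674b	AUAGCAUCAUCCAUCCUACCC	21	362	453	817
tae-miR9675	UUUAUGAUCACUCUCGUUUUG	21	0	32	0
tae-miR9676	UGGAUGUCAUCGUGGCCGUACA	22	57	63	19
tae-miR9677	UGGCCGUUGGUAGAGUAGGAGA	22	1	9	344
tae-miR9678	UCUGGCGAGGGACAUACACUGU	22	4	0	411
tae-miR9679	CAGAACCAGAAUGAGUAGCUC	21	15	32	59
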