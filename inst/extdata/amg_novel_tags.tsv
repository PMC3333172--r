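seq_id	sequence	count_am54	count_am48	target_gene
15212(24)	AGAUGGUGAGGGAUCCAGGACUAU	17	18	Populus trichocarpa F-box family protein
13039(24)	UGGACGUACUGAACAACAAUGAAG	25	20	Populus trichocarpa F-box family protein
278(21)	UAAUCUGCAUCCUGAGGUAUA	281	286	Populus trichocarpa F-box
1045(24)	GAGGACCGAGAUCAUAGAUGAAGA	121	104	Arabidopsis thaliana peroxidase, putative
666(21)	UUCAUUGUCUGUUCGGCCCUG	67	121	Zea mays typical P-type R2R3 Myb protein
1391(21)	UUUGGCAUUCUGUCCACCUCC	522	57	Populus trichocarpa f-box family protein, mRNA
2100(21)	AAACGGGGUUGUGGGAGAGCA	15	36	Populus EST from mild drought-stressed leaves
2511(21)	GAGCUCAUCUUAGGACACCUG	46	29	Populus EST from mild drought-stressed leaves
3079(21)	AAGGUCGGCCAGUGAGACGAU	16	23	Populus EST from mild drought-stressed leaves
4169(21)	GACUACAAUUCGGACGCCGGG	22	16	Populus EST from mild drought-stressed leaves
5876(21)	ACGAUACUGUAGGGGAGGUCC	13	10	Populus EST from mild drought-stressed leaves
6077(21)	AGCGUAGAUCCGGAGAUUCCC	16	10	Populus EST from mild drought-stressed leaves
166(22)	GCCGGCCGGGGGAGGGACUGGG	150	127	Populus EST from mild drought-stressed leaves
297(22)	GCCGUCCGGGGGACGGACUGGG	194	72	Populus EST from mild drought-stressed leaves
1182(22)	GCCGGCCGGGGGACGGACUGCG	104	20	Populus EST from mild drought-stressed leaves
80(23)	GAUGGAACAAUGUAGGCAAGGGA	89	158	Populus EST from mild drought-stressed leaves
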