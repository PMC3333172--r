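seq_id	sequence	family
87(21)	TTTGGATTGAAGGGAGCTCTA	amg-miR159
4(21)	TCGCTTGGTGCAGGTCGGGAA	amg-miR168
10(21)	AGAATCTTGATGATGCTGCAG	amg-miR172
622(21)	TTGGCATTCTGTCCACCTCCC	amg-miR394
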