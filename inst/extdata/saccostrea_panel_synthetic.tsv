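name	target_species	orientation	sequence	expected_product_bp
Sglo	S. glomerata	forward	GAGCACTTCGGGGTGTTCTA	185
Sglo	S. glomerata	reverse	AGGTGTTTCTCAGGTTGGAG	185
LinB	lineage B	forward	GCCTAACGTACCGTATGCGG	380
LinB	lineage B	reverse	TACCGGGATGTTAGGGTGCA	380
LinF	lineage F	forward	TGCTTGAGGACAGCGCGATA	310
LinF	lineage F	reverse	GCACGTTCATTCAACACCCA	310
LinG	lineage G	forward	CGGCCGATAGCAATATGTGA	244
LinG	lineage G	reverse	GCGTTCGCTACGAACAAATC	244
Sspa	S. spathulata	forward	GCGGTAGCTCTGTTGCGATG	100
Sspa	S. spathulata	reverse	ACGATTTAACTCGCGGATGA	100
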