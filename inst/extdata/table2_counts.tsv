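source	allele	self_proteome	immunogenic_overlapping	immunogenic_not_overlapping	nonimmunogenic_overlapping	nonimmunogenic_not_overlapping
frankild_hiv1	HLA-A*0201	human	4	29	18	36
assarsson_vaccinia	HLA-A*0201	mouse	3	15	8	18
perez_hiv1_non_a0201	non-HLA-A*0201	human	0	9	4	9
iedb_a0201	HLA-A*0201	human	54	143	230	362
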