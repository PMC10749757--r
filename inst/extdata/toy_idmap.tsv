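species	ensembl_id	entrez_id	symbol
human	ENSG0001	100	GeneA
human	ENSG0002	200	GeneB
human	ENSG0003	300	DUP
human	ENSG0004	400	DUP
human	ENSG0005	500	
mouse	ENSMUSG0001	101	Genea
mouse	ENSMUSG0002	201	Geneb
rat		301	GeneC
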