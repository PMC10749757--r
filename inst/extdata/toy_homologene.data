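3	9606	34	ACADM	4557231	NP_000007.1
3	10090	11364	Acadm	6680618	NP_031408.1
3	10116	24158	Acadm	292830	NP_058682.1
5	9606	37	ACADVL	4557235	NP_000009.1
5	10090	11370	Acadvl	23956084	NP_059062.1
5	7955	406283	acadvl	50540223	NP_001002366.1
5	6239	181757	acdh-9	17568389	NP_510197.1
12	9606	57	ACVRL1	4501895	NP_000011.1
12	10090	11482	Acvrl1	6752988	NP_033893.1
12	7227	42553	babo	24583886	NP_477024.1
22	9606	100	ADA	4557251	NP_000013.1
22	7955	565122	ada	161612316	NP_001098066.1
40	9598	465000	CHIMP1	111111	NP_111111.1
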