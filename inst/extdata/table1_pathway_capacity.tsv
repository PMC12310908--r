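taxon	amino_acid_synthesis	fatty_acid_biosynthesis	monosaccharides	nitrogen_metabolism	protein_degradation	resistance_to_antibiotics	toxic_compounds_resistance	vitamins	alkaloids_degradation	hormones	metabolism_of_aromatic_compounds	polysaccharides_degradation
Apilactobacillus	27	4	10	19	37	3	3	15	0	0	0	0
Bacillus	535	55	234	174	579	155	75	177	6	2	86	84
Carnobacterium	280	44	211	143	289	59	87	118	4	5	16	11
Enterobacter	783	123	562	379	663	233	193	235	12	3	189	150
Enterococcus	370	61	407	185	416	77	77	186	2	2	18	22
Gilliamella	217	47	136	102	184	41	21	81	4	4	31	46
Lactobacillus	142	15	169	97	225	33	42	83	0	1	8	8
Lactococcus	183	44	141	98	187	43	37	111	3	3	17	24
Staphylococcus	317	35	124	103	264	59	50	129	6	7	30	32
Weissella	218	50	150	120	215	49	23	138	0	0	12	12
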