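number	species	species_code	localization	start_nt	terc_like_length	terc_from	terc_to	its_length	orthologous_loci	empty_orthologs
1	Homo sapiens	HSA	HSA6	33092493	25	8	32	6	PTR, GGG, PPA, MMU, CJA, SBO	MMR, OGA
2	Homo sapiens	HSA	HSA18	73830841	31	15	45	14	PTR, GGG, PPA, MMU, CJA	ND
3	Microcebus murinus	MMR	MMR3	9808477	35	120	154	43	ND	OGA
4	Microcebus murinus	MMR	MMR4	11270478	27	142	168	43	ND	HSA, PTR, GGG, PPA, MMU, CJA, SBO, OGA
5	Microcebus murinus	MMR	MMR6	96205947	34	123	157	24	ND	HSA, PTR, GGG, PPA, OGA
6	Microcebus murinus	MMR	MMR14	66686502	36	127	162	32	ND	HSA, PTR, GGG, PPA, MMU, CJA, SBO, OGA
7	Microcebus murinus	MMR	MMR32	2429016	28	129	156	38	ND	HSA, PTR, GGG, PPA, MMU, CJA, SBO, OGA
8	Mus musculus	Mus	Mus1	46771696	31	341	374	57	ND	RNO
9	Mus musculus	Mus	Mus1	69071165	50	346	395	139	ND	RNO
10	Mus musculus	Mus	Mus4	119841389	42	351	392	53	ND	RNO
11	Mus musculus	Mus	Mus5	25644087	37	357	393	21	ND	RNO
12	Mus musculus	Mus	Mus6	67988979	44	351	394	93	ND	ND
13	Mus musculus	Mus	Mus8	23257793	38	351	388	213	RNO	ND
14	Mus musculus	Mus	Mus9	47869714	60	314	373	68	ND	RNO
15	Mus musculus	Mus	Mus10	20335691	98	289	388	108	ND	RNO
16	Mus musculus	Mus	Mus10	58382382	118	271	388	27	ND	RNO
17	Mus musculus	Mus	Mus11	86905013	38	343	381	55	ND	ND
18	Mus musculus	Mus	Mus12	7976282	68	316	384	77	RNO	ND
19	Mus musculus	Mus	Mus12	111293353	81	308	388	13	ND	RNO
20	Mus musculus	Mus	Mus13	3641558	54	331	384	22	RNO	ND
21	Mus musculus	Mus	Mus17	77320142	33	360	392	58	ND	RNO
22	Mus musculus	Mus	MusX	65734790	74	322	395	23	ND	RNO
23	Mus musculus	Mus	MusX	99124249	52	328	377	25	RNO	ND
24	Cricetulus griseus	CGR	CGR_scaffold364	1907954	49	332	380	60	ND	Mus, RNO
25	Cricetulus griseus	CGR	CGR_scaffold477	2816499	92	283	374	205	ND	ND
26	Cricetulus griseus	CGR	CGR_scaffold628	177514	44	336	379	35	ND	ND
27	Cricetulus griseus	CGR	CGR_scaffold2535	334947	98	283	380	113	ND	Mus, RNO
28	Oryctolagus cuniculus	OCU	OCU20	24654676	37	245	281	66	ND	LTI
29	Oryctolagus cuniculus	OCU	OCU_chrUn0052	1868849	20	148	167	39	ND	LTI
30	Bos taurus	BTA	BTA12	22246021	26	125	150	24	ND	OAR, SSC, TTR
31	Bos taurus	BTA	BTA20	7319073	24	124	147	23	ND	OAR, SSC, TTR
32	Sus scrofa	SSC	SSC7	70772067	29	139	167	40	ND	BTA, OAR
33	Equus caballus	ECA	ECA19	10034300	17	148	164	35	ND	EAS
34	Tapirus indicus	TIN	TIN_scaffold2309	127238	33	128	160	26	ND	CSS, ECA
35	Loxodonta africana	LAF	LAF_scaffold21	34372782	28	141	168	19	ND	PCA
36	Macropus eugenii	MEU	MEU_scaffold107834	53871	79	424	502	12	ND	SHA
37	Hirundo rustica	HRU	HRU5	20102963	42	106	146	10	ND	PDO, CMO
38	Xenopus laevis	XLA	XLA_2L	82565752	11	54	64	28	ND	XTR
39	Takifugu rubripes	TRU	TRU18	10170798	8	7	14	46	ND	ND
40	Scyliorhinus torazame	STO	STO_scyto00000011	2181744	31	233	263	30	ND	ND
41	Scyliorhinus torazame	STO	STO_scf_scyto00006538	68375	16	4	19	27	ND	ND
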