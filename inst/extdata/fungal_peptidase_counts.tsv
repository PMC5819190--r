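species	group	Serine	Aspartic	Metallo	Threonine	Cysteine	Glutamic	Asparagine	Mixed	Unknown
Aspergillus niger	mesophilic	204	15	110	24	79	5	0	0	0
Chaetomium globosum	mesophilic	177	29	123	26	110	4	0	0	0
Myceliophthora sepedonium	mesophilic	194	29	129	31	106	4	0	1	0
Mucor circinelloides	mesophilic	108	41	135	21	90	0	0	0	1
Penicillium chrysogenum	mesophilic	137	33	129	22	73	2	0	0	1
Penicillium roqueforti	mesophilic	381	36	203	36	146	4	4	0	10
Rhizopus delemar	mesophilic	122	75	126	34	107	0	0	0	0
Talaromyces stipitatus	mesophilic	180	164	145	105	82	9	0	0	1
Aspergillus fumigatus	thermotolerant	137	9	101	22	77	2	0	1	0
Rhizopus microsporus	thermotolerant	181	53	212	39	167	0	0	0	0
Chaetomium thermophilum	thermophilic	85	22	74	26	66	4	0	0	0
Myceliophthora fergusii	thermophilic	85	18	81	23	71	3	0	0	0
Myceliophthora thermophila	thermophilic	108	23	86	26	73	4	0	0	0
Myriococcum thermophilum	thermophilic	106	23	82	28	76	3	0	0	0
Rasamsonia byssochlamydoides	thermophilic	115	16	84	24	70	2	0	0	0
Rhizomucor pusillus	thermophilic	106	35	109	18	79	0	0	0	0
Thermoascus crustaceus	thermophilic	122	21	87	23	72	1	0	0	0
Thermomucor indicae-seudaticae	thermophilic	78	29	101	22	67	0	0	0	0
Thermomyces dupontii	thermophilic	66	11	71	22	68	4	0	0	0
Thermomyces lanuginosus	thermophilic	63	14	72	22	70	5	0	0	0
Thermomyces stellatus	thermophilic	104	14	83	28	76	0	2	0	0
Thielavia australiensis	thermophilic	89	22	78	26	76	1	0	1	0
Thielavia terrestris	thermophilic	110	31	84	26	75	5	0	0	0
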