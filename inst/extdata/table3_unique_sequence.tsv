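sequence	mir_name	fold_change	epi_mean	epi_sem	endo_mean	endo_sem
TACCCTGTAGAACCGAATTTG	rno-mir-10b(P)	-2.99	140.45	22.37	46.95	18.79
CTGGACGCGAGCCGGGCCCTT	mmu-mir-5115(MSupV)	-2.82	753.60	405.10	267.59	109.66
TACCCTGTAGAACCGAATTTGT	rno-mir-10b(MSub/Sup)	-2.54	2108.85	325.91	829.98	294.94
ATCCCACTTCTGACACCA	bta-mir-2478(MSub)	-2.45	196.81	33.86	80.26	6.23
CCGCGTCGGCGGTTCCC	nlo-mir-125(PV)	-2.43	138.79	42.98	57.12	25.49
ACCCTGTAGAACCGAATTTGT	rno-mir-10b(MSub/Sup)	-2.42	119.77	21.71	49.43	15.33
TACCCTGTAGATCCGAATTTGA	rno-mir-10a(MSubV)	-2.22	325.04	20.21	146.52	55.43
CTGGACGCGAGCCGGGCCCTTCCC	mmu-mir-5115(PV)	-2.21	147.76	43.14	67.01	26.00
TCGTACCGTGAGTAATAATGC	rno-mir-126(MSub)	-2.17	821.18	347.35	378.83	99.04
TACCACAGGGTAGAACCACGGAA	rno-mir-140(M*SupV)	-2.16	348.57	66.62	161.25	22.11
ACCCTGTAGATCCGAATTTG	rno-mir-10a(MSub)	-2.14	272.77	37.62	127.17	50.55
ACCCTGTAGATCCGAATTTGT	rno-mir-10a(MSub)	-2.11	1779.84	246.64	842.11	327.87
CTGGACGCGAGCCGGGC	mmu-mir-5115(MSubV)	-2.10	508.53	119.83	241.60	100.94
TACCCTGTAGAACCGAATTTGTG	rno-mir-10b(MSub/Sup)	-2.09	192.96	12.82	92.16	32.52
TACCCTGTAGATCCGAATTT	rno-mir-10a(P)	-2.08	349.57	32.37	168.25	69.42
CTGGACGCGAGCCGGGCCCTTCC	mmu-mir-5115(PV)	-2.05	188.96	62.04	92.07	34.57
CTGGACGCGAGCCGGGCCCTTC	mmu-mir-5115(MSupV)	-2.04	775.70	233.89	380.53	157.79
AACCCGTAGATCCGAACTTGTGA	rno-mir-100(MSupV)	-2.01	768.45	357.07	382.85	189.43
TGTAAACATCCTCGACTGGAAGCG	rno-mir-30a(MSupV)	2.06	118.32	23.96	243.52	139.23
TCCTGTACTGAGCTGCCCCGG	bta-mir-486(MSubV)	2.39	133.14	28.86	318.16	181.42
GGGGGGCCCAAGTCCTTCTGATCGAGGCCC	mmu-mir-5105(P)	2.93	73.61	16.57	215.65	93.91
CATTCAACGCTGTCGGTGAGT	rno-mir-181a-2//mir-181a-1(MSub)	40.70	6.08	0.93	247.35	243.97
CATTCAACGCTGTCGGTGAG	rno-mir-181a-2//mir-181a-1(MSub)	63.29	2.65	0.93	167.78	165.76
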