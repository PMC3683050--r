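mir_name	fold_change	epi_mean	epi_sem	endo_mean	endo_sem
rno-mir-31	3.00	4.45	2.62	13.36	3.49
rno-mir-326	1.92	12.52	0.98	24.06	2.03
rno-mir-872	1.80	11.42	2.54	20.61	5.32
rno-mir-1249	1.66	62.40	12.09	103.28	28.92
rno-mir-503*	1.64	5.02	1.45	8.21	0.65
rno-mir-193	1.54	14.14	2.23	21.82	8.28
rno-mir-872*	1.53	51.11	7.20	78.40	14.18
mmu-mir-1983	1.53	8.16	3.02	12.45	2.99
rno-mir-145	1.50	1038.98	188.02	1558.55	346.49
rno-mir-10a	-1.51	1967.41	189.80	1305.65	527.54
rno-mir-9-1//mir-9-3//mir-9-2	-1.52	64.65	13.48	42.62	11.51
rno-mir-208	-1.52	12.33	3.51	8.09	3.41
rno-mir-132	-1.61	18.32	1.35	11.37	2.24
rno-mir-138-2//mir-138-1	-1.66	17.24	2.76	10.36	4.83
rno-mir-210*	-1.69	7.65	1.69	4.53	1.10
rno-mir-100	-1.70	2089.07	827.35	1230.28	597.96
rno-mir-133b	-1.70	15.27	4.06	8.98	2.54
rno-mir-133a*	-1.72	206.39	59.22	120.26	27.43
rno-mir-17-1//mir-17-2	-1.81	10.74	1.68	5.93	0.32
rno-mir-322*	-1.98	20.39	8.69	10.31	5.30
mmu-mir-720	-2.00	23.31	5.27	11.66	1.00
rno-mir-425	-2.25	15.66	3.01	6.96	3.58
hsa-mir-720	-2.30	39.25	8.00	17.09	2.93
rno-mir-374	-2.49	8.51	3.73	3.42	0.66
rno-mir-410	-2.88	56.31	2.35	19.58	5.31
hsa-mir-4492	-2.92	26.70	10.82	9.14	4.45
rno-mir-200b	-5.88	13.39	10.25	2.28	1.23
rno-mir-547*	-9.73	6.82	3.21	0.70	0.70
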