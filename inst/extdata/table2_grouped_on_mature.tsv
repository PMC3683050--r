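mir_name	fold_change	epi_mean	epi_sem	endo_mean	endo_sem
rno-mir-200b	-4.26	25.92	16.66	6.08	3.31
rno-mir-410	-2.87	70.10	3.37	24.41	5.32
mmu-mir-690	-2.55	12.73	3.72	5.00	1.39
rno-mir-10b	-2.51	3064.12	431.15	1221.18	441.95
mmu-mir-720	-2.20	27.78	6.87	12.63	1.12
mmu-mir-351	-2.08	11.37	2.93	5.47	0.60
hsa-mir-4485	-2.07	9.81	2.27	4.75	1.81
rno-mir-341	-2.05	7.78	2.10	3.80	2.45
mmu-mir-5115	-1.99	5823.13	1542.50	2930.00	1218.62
rno-mir-384	-1.97	8.73	2.79	4.43	1.46
bta-mir-2478	-1.96	358.54	67.41	182.69	21.31
hsa-mir-720	-1.96	68.26	12.81	34.90	6.30
hsamir-4492	-1.92	43.13	13.29	22.46	9.31
cbr-mir-1	-1.91	10.46	4.84	5.47	1.06
rno-mir-10a	-1.87	30279.72	3036.38	16169.54	6084.64
hsa-mir-1260a	-1.77	278.56	53.99	157.62	42.34
rno-mir-338	-1.77	117.08	1.79	66.29	7.61
mmu-mir-5102	-1.73	11.49	3.65	6.65	1.16
rno-mir-138-2//mir-138-1	-1.71	27.70	5.62	16.18	8.01
rno-mir-100	-1.70	5514.57	2226.60	3245.17	1552.80
rno-mir-132	-1.63	37.90	2.55	23.21	4.82
rno-mir-9-1//mir-9-3//mir-9-2	-1.58	169.45	26.81	107.12	26.08
ssc-mir-186	-1.57	16.66	5.25	10.60	1.13
dre-mir-26b	-1.54	25.55	7.97	16.64	2.29
cte-mir-1	-1.53	6.37	1.86	4.17	1.71
gga-mir-3535	-1.52	9.46	0.21	6.24	1.83
rno-mir-374	-1.52	64.17	18.59	42.34	7.63
rno-mir-411	-1.50	39.14	3.72	26.11	4.25
rno-mir-145	1.50	1537.62	272.14	2300.09	506.26
ola-mir-27d	1.50	6.30	1.14	9.42	3.09
gga-mir-193b	1.51	28.48	5.52	42.86	6.54
mmu-mir-101c	1.56	7.32	2.86	11.39	0.42
rno-mir-326	1.57	37.54	1.72	59.00	5.46
bta-mir-1306	1.63	5.20	1.59	8.45	0.66
rno-mir-877	1.64	8.05	1.21	13.20	1.75
sha-mir-716a	1.75	8.22	0.13	14.37	6.10
rno-mir-674	2.15	5.44	0.81	11.67	1.74
rno-mir-31	2.54	9.37	4.26	23.78	6.64
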