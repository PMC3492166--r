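primer_set	family	level	dap10	dap15	dap18	dap25
Common_B	B	family	82.86	85.44	80.69	80.43
B1	B	subfamily	35.02	34.94	29.06	15.84
B1a	B	subgroup	12.29	12.20	10.06	7.45
X87232	B	member	NA	NA	NA	NA
JQ867084	B	member	NA	NA	NA	NA
DQ148297	B	member	NA	NA	NA	NA
B2	B	subfamily	0.40	0.40	0.40	0.19
B3	B	subfamily	35.13	23.54	28.38	33.75
B3a	B	subgroup	20.76	15.26	18.64	27.76
B3b	B	subgroup	NA	NA	NA	NA
B3c	B	subgroup	0.05	0.02	0.02	0.02
DQ826387	B	member	0.20	0.14	0.17	0.09
GQ342976	B	member	0.19	0.31	0.47	0.99
JQ867088	B	member	NA	NA	NA	NA
Common_C	C	family	5.73	5.16	6.59	8.72
C1	C	subfamily	0.05	0.08	0.11	0.18
S66938	C	member	3.85	4.58	5.08	5.73
Common_D	D	family	1.55	2.57	2.48	1.89
Common_gamma1	gamma1	family	4.02	1.86	2.95	1.57
AJ580585	gamma1	member	NA	NA	NA	NA
X13508	gamma1	member	NA	NA	NA	NA
Common_gamma3	gamma3	family	5.84	4.98	7.30	7.39
X72628	gamma3	member	NA	NA	NA	NA
JQ867080	gamma3	member	NA	NA	NA	NA
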