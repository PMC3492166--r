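dap	numerator	denominator	mean_ratio	sd_ratio
10	Actin	Ubiquitin	0.16	0.01
10	Actin	PTF	0.12	0.01
10	Ubiquitin	Actin	6.15	0.19
10	Ubiquitin	PTF	0.72	0.02
10	PTF	Actin	8.56	0.33
10	PTF	Ubiquitin	1.39	0.05
15	Actin	Ubiquitin	0.13	0.03
15	Actin	PTF	0.17	0.04
15	Ubiquitin	Actin	7.53	0.48
15	Ubiquitin	PTF	1.26	0.08
15	PTF	Actin	6.57	0.23
15	PTF	Ubiquitin	0.79	0.14
18	Actin	Ubiquitin	0.14	0.03
18	Actin	PTF	0.20	0.04
18	Ubiquitin	Actin	6.17	0.93
18	Ubiquitin	PTF	1.42	0.34
18	PTF	Actin	5.99	0.24
18	PTF	Ubiquitin	0.71	0.24
25	Actin	Ubiquitin	0.11	0.00
25	Actin	PTF	0.08	0.00
25	Ubiquitin	Actin	9.21	0.32
25	Ubiquitin	PTF	0.70	0.02
25	PTF	Actin	13.19	0.38
25	PTF	Ubiquitin	1.44	0.04
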