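primer_set	added_amol	calculated_mean	calculated_sd
Common_B	5.16	5.71	0.18
B1	2.94	2.92	0.11
B1a	2.94	2.74	0.55
JQ867084	0.63	0.54	0.14
B3	2.21	2.41	0.61
B3a	2.21	1.81	0.11
B3b	0.88	1.09	0.02
Common_C	0.53	0.51	0.02
Common_D	0.43	0.51	0.01
Common_gamma1	1.04	0.97	0.07
Common_gamma3	0.54	0.56	0.00
JQ867080	0.54	0.47	0.07
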