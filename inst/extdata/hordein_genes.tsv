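family	accession	cultivar	coding_length_bp	aa_residues
B	JQ867081	Golden Promise	804	267
B	JQ867082	Golden Promise	837	278
B	JQ867083	Golden Promise	861	286
B	JQ867084	Golden Promise	762	253
B	JQ867085	Golden Promise	933	310
B	JQ867086	Golden Promise	855	284
B	JQ867087	Golden Promise	840	279
B	JQ867088	Golden Promise	933	310
B	JQ867089	Golden Promise	834	277
B	GQ342970	Z26	798	265
B	GQ342971	Z26	798	265
B	GQ342972	Z26	798	265
B	GQ342973	Z26	798	265
B	GQ342975	Z26	798	265
B	GQ342976	Z26	798	265
B	DQ267478	ZQ7239	798	265
B	DQ826387	ZQ148	873	265
B	X03103	Sundance	882	293
B	DQ148297	XQ053	903	300
B	X87232	Carlsberg II	816	271
B	JQ859915	Barke	873	290
B	JQ859916	Barke	816	271
B	JQ859917	Barke	783	260
B	JQ867073	Barke	885	294
B	JQ867074	Barke	873	290
B	JQ867075	Barke	873	290
B	DQ267479	Aba-zhangla	894	297
B	DQ178602	Aba-siqing	873	290
B	X53690	Moskovsky 3	873	290
C	S66938	Odessky 46	1017	338
C	X60037	Bomi	867	288
C	JQ867090	Barke	909	302
D	AY268139	Morex	2274	757
D	D82941	Haruna Nijo	2124	707
D	JQ867076	Golden Promise	2244	747
D	JQ867077	Golden Promise	2184	727
D	JQ867091	Barke	2244	747
gamma1	X13508	Carina	918	305
gamma1	AJ580585	Riso 56	768	255
gamma1	JQ867078	Barke	918	305
gamma1	JQ867079	Golden Promise	888	295
gamma3	X72628	Carlsberg II	855	284
gamma3	JQ867080	Golden Promise	918	305
Actin	AY145451	Himalaya	1133	377
Ubiquitin	AK249354	Haruna Nijo	471	156
PTF	AK252057	Haruna Nijo	348	115
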