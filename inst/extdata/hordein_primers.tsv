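name	family	level	forward	reverse
Common_B	B	family	TTTCCAACAACCTCAACCACA	GTAGGGTACGCAGCGCAAT
B1	B	subfamily	GCAAGAACAACCCCAACAGTC	GTAGGGTACGCAGCGCAAT
B1a	B	subgroup	CCAGCAACTGCCGCAAATCT	CAACTGTTGTTGGGTTTGGGAT
DQ148297	B	member	CCACTCCAGCTAGCTCAC	TGCCGAATGGAAGTATGCG
X87232	B	member	GGGCTACAACAACCAATTCTG	CCTTGTGGGAGTGGTGTTG
JQ867084	B	member	CCAACAGTCGGTCCAAGGA	CATTGTCCAACTTTCTCCTGC
B2	B	subfamily	CCGCAGCAAGTCGGACAA	CCTGTTGTTGTTGACCAAC
B3	B	subfamily	GTGCAATCGTCTACTCTATCG	GGGAGACACCTTGGACCAAT
B3a	B	subgroup	CTATCGTCCTGCGAGAACAAT	CCGACTTGTTGCTGTTGTG
B3b	B	subgroup	ACGTATTGCAAGGTCGCAG	CGGCAGTTGTTGGCAACAC
B3c	B	subgroup	AAACAACAGCAAGTGCCACAT	TCGCCTCAAGCTGAGCTAG
DQ826387	B	member	CCTCAACCACAACAAGTTGGC	CTGTACGACGGCACATTAACAC
GQ342976	B	member	CTCCTACAAGAACAACAAGAC	CCTTGCATGGGTTTAGCTGC
JQ867088	B	member	AACAACAGTCGCAGCTACAT	TTCAAGCTGAGCTAGCTGGA
Common_C	C	family	TAATTCCCCAGCAACCTCAA	CCATACTCCAGATGGTTTGTTG
C1	C	subfamily	TCAACCAGTCCCCCAGCA	CTTGTTGGGGTTGCGGTT
S66938	C	member	CCTCAACAACCATTTCCCCT	AAATGGTTGTTGTGGTTGCCA
Common_D	D	family	CACCGTGTCTCTGCACCATG	TGCCGTAGTACAACTCGTTGG
Common_gamma1	gamma1	subfamily	CAACCGCAACAACTAGCTCA	CACCAACAAATGGTGCTTTG
AJ580585	gamma1	member	CCAACAACAACTGAATCCGTA	TTGCAGGCAACATTGTTGCA
X13508	gamma1	member	CCTGTGTCATTGTTATCGTACA	CGACAACTGCTCTGTTGCAC
Common_gamma3	gamma3	subfamily	GGTTGGGTCATTGGTGATTC	AGCAATAAGGTGGGACATGC
X72628	gamma3	member	AGCAAATATCAATGAGCAG	GAGATTGGACAAAACCATGAC
JQ867080	gamma3	member	AGCAAATATCAATGAGCAA	GAGATTGGACAAAACCATGAT
Actin	Actin	reference	CCTCAGTTGAGAAGAGCTACG	TCTGCGCCAATCGTGATC
Ubiquitin	Ubiquitin	reference	TCAAGGTGAAGACACTTACTGG	CATAGATGAGCCTCTGTTGAAC
PTF	PTF	reference	CTATGTGCATGTGCGTGTC	CTTGAGAATCTTGTTGTAGCTG
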