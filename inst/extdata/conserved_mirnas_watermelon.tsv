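family	name	sequence	length	Wm_Wm	Wm_BG	Wm_Sq
miR156	miR156f	TTGACAGAAGATAGAGAGCAC	21	1495	1186	524
miR159	miR159a	TTTGGATTGAAGGGAGCTCTA	21	97973	73719	26273
miR160	miR160a	TGCCTGGCTCCCTGTATGCCA	21	2481	3181	2830
miR162	miR162a	TCGATAAACCTCTGCATCCAG	21	103	107	44
miR164	miR164a	TGGAGAAGCAGGGCACGTGCA	21	1254	1614	353
miR166	miR166a	TCGGACCAGGCTTCATTCCCC	21	47770	55967	39253
miR167	miR167	AGATCATGTGGCAGTTTCACC	21	0	9	0
miR167	miR167a	TGAAGCTGCCAGCATGATCTA	21	638	566	23960
miR167	miR167c	TGAAGCTGCCAGCATGATCTGG	22	89803	101182	0
miR168	miR168a	TCGCTTGGTGCAGGTCGGGAA	21	1326	1142	825
miR169	miR169a	CAGCCAAGGATGACTTGCCGG	21	209	235	251
miR169	miR169c	TGAGCCAAGGATGACTTGCCG	21	17	7	0
miR169	miR169n	TAGCCAAAGATGACTTGCCTG	21	12	0	0
miR171	miR171a	TTGAGCCGTGCCAATATCACG	21	20	47	652
miR171	miR171c	TGATTGAGCCGTGCCAATATC	21	1805	1729	627
miR172	miR172	GGAATCTTGATGATGCTGCAG	21	206	262	43
miR319	miR319a	TTGGACTGAAGGGTGCTCCCT	21	8653	24804	0
miR319	miR319c	TTGGACTGAAAGGAGCTCCT	20	1200	1106	0
miR390	miR390a	AAGCTCAGGAGGGATAGCGCC	21	461	599	332
miR393	miR393	TCCAAAGGGATCGCATTGATC	21	220	177	60
miR395	miR395a	CTGAAGTGTTTGGGGGAACTC	21	430	216	6
miR396	miR396	TTCCACAGCTTTCTTGAACTT	21	9	11	798
miR396	miR396a	TTCCACAGCTTTCTTGAACTG	21	3906	323	8
miR397	miR397	TCATTGAGTGCAGCGTTGATG	21	72	37	4
miR398	miR398a	TGTGTTCTCAGGTCACCCCTT	21	130	5444	277
miR398	miR398b	TGTGTTCTCAGGTCGCCCCTG	21	0	0	8
miR399	miR399a	TGCCAAAGGAGAGTTGCCCTG	21	0	0	3
miR399	miR399g	TGCCAAAGGAGAATTGCCCTG	21	0	3	0
miR408	miR408	ATGCACTGCCTCTTCCCTGGC	21	8865	4017	288
miR477	miR477a	CTCTCCCTCAAGGGCTTCTA	20	0	11	19
miR530	miR530b	TGCATTTGCACCTGCACCTT	20	29	40	24
miR827	miR827	TTAGATGACCATCAACAAACG	21	83	59	15
miR894	miR894	CGTTTCACGTCGGGTTCACC	20	6005	6896	6250
miR1310	miR1310	GGCATCGGGGGCGTAACGCCCCT	23	0	4	0
miR166l	miR166l	TCGGACCAGGCTTCATTCCTC	21	0	1972	2621
miR2111	miR2111a	TAATCTGCATCCTGAGGTCTA	21	3064	3899	2741
miR2911	miR2911	GGCCGGGGGACGGGCTGGGA	20	6785	7658	5590
miR2916	miR2916	TGGGGACTCGAAGACGATCATAT	23	78	88	174
miR4414	miR4414	AGCTGCTGACTCGTTGGCTC	20	15	8	24
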