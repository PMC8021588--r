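pair_id	fwd_name	fwd_seq	rev_name	rev_seq
1	1_f_180	AACGCGCTGCGAGCCTGTGA	1_r_369	CCCACAAGGGTTAGGCCACT
2	1_f_180	AACGCGCTGCGAGCCTGTGA	1_r_397	ATCGCCGATCCCACCTTCGA
3	1_f_180	AACGCGCTGCGAGCCTGTGA	1_r_400	CCAATCGCCGATCCCACCTT
4	1_f_180	AACGCGCTGCGAGCCTGTGA	1_r_408	ACTTCGTCCCAATCGCCGAT
5	1_f_186	CTGCGAGCCTGTGAGGGTGA	1_r_369	CCCACAAGGGTTAGGCCACT
6	1_f_186	CTGCGAGCCTGTGAGGGTGA	1_r_397	ATCGCCGATCCCACCTTCGA
7	1_f_186	CTGCGAGCCTGTGAGGGTGA	1_r_400	CCAATCGCCGATCCCACCTT
8	1_f_186	CTGCGAGCCTGTGAGGGTGA	1_r_408	ACTTCGTCCCAATCGCCGAT
9	2_f_50	TCAGTTGGGCACTCGTAAGG	2_r_342	TGGCAAAGACCACTTCGGGT
10	4_f_251	CTAAAGCCACCCCCAGTTCA	4_r_395	CTCTTCGCCTGACTTCGGGT
11	4_f_251	CTAAAGCCACCCCCAGTTCA	4_r_403	TCGGCAGGCTCTTCGCCTGA
12	5_f_0	TGCCTGGGAGCCCTAGCACA	5_r_228	CCCCTTACGGGTTCGCTTCC
13	5_f_223	CAGAGGGAAGCGAACCCGTA	5_r_410	TCCGGGGGTTGGGATAGCGA
14	6_f_66	GCCTAGCAATAGGATCTCTC	6_r_211	GGGCATAGTTTAGGGATTGG
15	6_f_211	CCAATCCCTAAACTATGCCC	6_r_363	AGACGACCTGAGCACTTCTG
16	6_f_211	CCAATCCCTAAACTATGCCC	6_r_385	TACTAATCACAACTTAGGGC
17	7_f_205	AATCCCTTAAAAGCTGTCTC	7_r_347	AGCGTCTTTGGGTACTCCTG
18	8_f_78	ACTGCCCAGATCAACTGGGA	8_r_349	TGGCTTCAGATACTTCGGGT
19	8_f_78	ACTGCCCAGATCAACTGGGA	8_r_359	TCCTTGCGGTTGGCTTCAGA
20	9_f_87	GACTGCCCGCGAAAGCGGGA	9_r_181	GTTGCCGGGTGGCATCGCTT
21	10_f_226	TCCCTAAAAAGCATCCTCAG	10_r_381	AGGCGGAGTTGGGTCACTGA
22	12_f_190	GGCATATACAAAGAGAAGCG	12_r_395	TAAGCGCCCTCCCGAAGGTT
23	12_f_216	CGAGAGCAAGCGGACCTCAT	12_r_395	TAAGCGCCCTCCCGAAGGTT
24	12_f_236	AAAGTATGTCGTAGTCCGGA	12_r_395	TAAGCGCCCTCCCGAAGGTT
25	13_f_203	GGTACAAAGAGCTGCAAGAC	13_r_397	CTCCAAAAAGGTTACCCCAC
26	14_f_64	GCAAGGGGGCCCTCTGGAGA	14_r_341	TAGAGCACTCCCTTCTCCCA
27	15_f_60	TGGCGAAACCGCCTCGGATA	15_r_349	CTCCCTTGCGGTTAGCGCAC
28	18_f_17	TGTCGGTAGTTACAGGTGTC	18_r_177	GATCTGCACTGAGACCACGT
29	18_f_173	CTAAACGTGGTCTCAGTGCA	18_r_330	TCCCCGACTGGGGTTAGCAC
30	19_f_83	TAGTGGGACAGCCGGAGTAA	19_r_177	AGGTCGCATCCCGTTGTCCT
31	19_f_90	ACAGCCGGAGTAATCCGGAG	19_r_371	CTATCCGAAGATTCGGTCAC
32	19_f_196	TCGCGAGAGTGAGCCAACCT	19_r_346	TCTGGCAAAACCGACTTTCG
33	19_f_196	TCGCGAGAGTGAGCCAACCT	19_r_371	CTATCCGAAGATTCGGTCAC
34	20_f_225	ATCCCAAAATCCTCTCTCAG	20_r_382	GACGATCCTTGCGGTTACGT
35	21_f_61	GGGTAATGCCGGGTACTCAC	21_r_211	ACCACGACAGGGTTTAGGGG
36	21_f_61	GGGTAATGCCGGGTACTCAC	21_r_217	ATCTGCACCACGACAGGGTT
37	21_f_61	GGGTAATGCCGGGTACTCAC	21_r_227	GCAACCCTCAATCTGCACCA
38	21_f_179	AATGGGCTGCAACGCCGTAA	21_r_359	GTTAGCTCGGGGACTTCCGA
39	21_f_216	AAACCCTGTCGTGGTGCAGA	21_r_348	GACTTCCGATGAACCCGACT
40	23_f_151	ATGACGTCAGGTACTCGTGC	23_r_437	CCCCCCTCACCAGGTTCTCC
41	24_f_84	CTGCCAACGTAAGTTGGAGG	24_r_360	CTTGCGGTTAGCAACACGGT
42	26_f_74	AGACTGCCCGTGTTAAGCGG	26_r_169	TCACTATGTCGCTGCCCTTT
43	26_f_74	AGACTGCCCGTGTTAAGCGG	26_r_358	CTGCAAGCAGGTTGGCGCAA
44	28_f_165	AATGGGGCGGACAGAGCGTT	28_r_333	CCCCCGCTTTGGTGGCTTGA
45	28_f_165	AATGGGGCGGACAGAGCGTT	28_r_397	ACTTAGTCCCCATCACGGGT
46	28_f_170	GGCGGACAGAGCGTTGCTAG	28_r_339	GGATGCCCCCCGCTTTGGTG
47	28_f_173	GGACAGAGCGTTGCTAGGCT	28_r_333	CCCCCGCTTTGGTGGCTTGA
48	28_f_192	TGCAAAGTCATGCTAATCGC	28_r_333	CCCCCGCTTTGGTGGCTTGA
49	28_f_192	TGCAAAGTCATGCTAATCGC	28_r_397	ACTTAGTCCCCATCACGGGT
50	28_f_204	CTAATCGCAAAAACCGTTCC	28_r_397	ACTTAGTCCCCATCACGGGT
51	29_f_237	GCGAATCTCAGAAAGCGCTC	29_r_437	CCCAGTCGCCAGCCATACCA
52	30_f_128	CAATGCTACGGACAAAGGGC	30_r_306	TTCGGGCGTGGCCAACTTCC
53	30_f_128	CAATGCTACGGACAAAGGGC	30_r_328	CCACAAGGGTTGGAGTAACG
54	30_f_128	CAATGCTACGGACAAAGGGC	30_r_342	TTCGGCGTCCTCCTCCACAA
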