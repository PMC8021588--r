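pair_id	fwd_name	fwd_seq	rev_name	rev_seq
1	aim_1f	GTCCAGGGCTTCACACATGCTA	aim_22r	TGTTACCAACTTTCATGACGTG
2	aim_71f	AGCGCAACCCTCACCTTATGTT	aim_94r	GGGACCGGATTTTTGAGATTAG
3	aim_122f	TTCAGTTGGGCACTCGTAAGGA	aim_94r	GGGACCGGATTTTTGAGATTAG
4	aim_94f	CTAATCTCAAAAATCCGGTCCC	aim_143r	CCTTCACGAGTTTCACCTTAGT
5	aim_94f	CTAATCTCAAAAATCCGGTCCC	aim_147r	CTTCACCCCCTTCACGAGTTTC
6	aim_161f	GAGGTGGAGCGAATCCCAGAAA	aim_194r	CTTACCAAGCATACCTTAGGCA
7	aim_263f	CAAATCCCAGAAAGCCGCTCTC	aim_250r	ACCAGCCCTGCCGTCGGCGCCT
8	aim_348f	GTGTTGCCTAGCAATAGGATCT	aim_282r	TGCTGCCCTCTGTCTATGCCAT
9	aim_386f	GCTGAGGACTCTAATTGAACTG	aim_394r	AGACAGCTTTTAAGGGATTTCC
10	aim_386f	GCTGAGGACTCTAATTGAACTG	aim_461r	CCGATCCGGACTGAGACAGCTT
11	aim_394f	GGAAATCCCTTAAAAGCTGTCT	aim_436r	CGAGCGTCTTTGGGTACTCCTG
12	aim_468f	GGCGGAGGAAATCCTAAAAACT	aim_515r	CTTCAGATACTTCGGGTGCGAC
13	aim_555f	ACGGGACTGCCCGCGAAAGCGG	aim_562r	GGGCCCACCTTTTTGCGATTAG
14	aim_599f	GTGCTACAACGGGTAGCGAAAC	aim_652r	CCGCCGAGGCGGAGTTGGGTCA
15	aim_764f	CTTATCCTTTGTTGCCAGCGGT	aim_744r	CGACATACTTTATGAGGTCCGC
16	aim_812f	CTGCCAGTGATAAACTGGAGGA	aim_744r	CGACATACTTTATGAGGTCCGC
17	aim_842f	TCTCATAAAACCGTTCTCAGTT	aim_848r	TGTTACAAACTCTCGTGGTGTG
18	aim_1016f	CTAATCGGAAAAAGCCGGCCTC	aim_1036r	ATGAATTACACCTTGGGCGGCT
19	aim_1209f	GTGTCGGTAGTTACAGGTGTCT	aim_1159r	ATTGTCGTGGCCATTGTAGCGT
20	aim_1248f	CGCCGTGACCGGCGGAGGAAGG	aim_1193r	CCGCGCCATGGCTGATACGCGG
21	aim_1175f	TCGCCTAAACGTGGTCTCAGTG	aim_1264r	TCCCAGTCGCGGCCCCTGCCCT
22	aim_1177f	GCCTAAACGTGGTCTCAGTGCA	aim_1264r	TCCCAGTCGCGGCCCCTGCCCT
23	aim_1316f	CTAGTGGGACAGCCGGAGTAAT	aim_1285r	TGCAATCCGAACTAAGACAAGG
24	aim_1332f	CCGGAGTAATCCGGAGGAAGGT	aim_1276r	AGGTTTTTGAGGTTGGCTCACT
25	aim_1285f	CCTTGTCTTAGTTCGGATTGCA	aim_1293r	GCTTCTGGCAAAACCGACTTTC
26	aim_1401f	TGAGGTGTCGGCTTAAGTGCCA	aim_1368r	GCTAGCTGCCTTCTGTACCCCC
27	aim_1401f	TGAGGTGTCGGCTTAAGTGCCA	aim_1383r	TTTGGGATTAGCATACGGTCAC
28	aim_1415f	GAGGTGTCGGCTTAAGTGCCAT	aim_1368r	GCTAGCTGCCTTCTGTACCCCC
29	aim_1447f	AGGTCATGCTGAGGACTCTGGA	aim_1368r	GCTAGCTGCCTTCTGTACCCCC
30	aim_1447f	AGGTCATGCTGAGGACTCTGGA	aim_1391r	TTCGATCCGAACTGAGAGAGGA
31	aim_1391f	TCCTCTCTCAGTTCGGATCGAA	aim_1465r	CCCTAGGACGATCCTTGCGGTT
32	aim_1549f	GGGTAATGCCGGGTACTCACAG	aim_1504r	CATTGTCCCTGCCACTGTAGCG
33	aim_1504f	CGCTACAGTGGCAGGGACAATG	aim_1550r	TAGCTCGGGGACTTCCGATGAA
34	aim_1758f	GCCAATACAAACAGTTGCAAAT	aim_1775r	TACCAGCTCTCATAGTTTGACG
35	aim_1770f	CTGTAAAGTTGGTCTCAGTTCG	aim_1775r	TACCAGCTCTCATAGTTTGACG
36	aim_1770f	CTGTAAAGTTGGTCTCAGTTCG	aim_1811r	CTACCCTAGACATGCGCTTCCT
37	aim_1948f	CAAAGGGCAGCGACATAGTGAT	aim_1984r	ATGAGCCGTAGCTGATGCCCAT
38	aim_2085f	AGTACAGAAGGTAGCAAGATCG	aim_2138r	AACGTATTCACGGCGTTATGGC
39	aim_2109f	GATGGAGCAAATCCTTAAAGCT	aim_2164r	TCAACGACTTAAGGTAAAACCA
40	aim_2292f	GGTTAAGTCCCCTAACGAGCGA	aim_2247r	ATGACTTTGCAGCCTAGCAACG
41	aim_2547f	TCGAGTACATGAAGTTGGAATC	aim_2581r	TACGGTTAGGCCTGCTACTTCA
42	ai2_1242_f	TACTTTGTCTAACGAGACTGCC	ai2_1242_r	CGAACTGAGACCAACTTTACAG
43	ai2_100_f	ACGAGCCGGAGGAAGGAGG	ai2_100_r	ACCCCGGGAACGTATTCACC
44	ai2_1213_f	CCTAAACCCTGTCGTGGTGCAG	ai2_1213_r	TAGCTCGGGGACTTCCGATGAA
45	ai2_1325_f	TAAGGGGACTGCCCCGGATAAC	ai2_1325_r	GCGCTTTCTGAGATTCGCTCAG
46	ai2_6_f	CAAGTCGAGCGGAGAAGATTT	ai2_6_r	GGTATTACCCATCCTTTCGGAT
47	ai2_1194_f	GCGGGTGACCGTATGCTAATCC	ai2_1194_r	CTTGCGGTTACGTACTTCAGGT
48	ai2_1315_f	CGTTGCTAGGCTGCAAAGTCAT	ai2_1315_r	GCGGCTCCGGCGACTTCGGATG
49	ai2_1147_f	CGCCGTGACCGGCGGAGGAAGG	ai2_1147_r	CACTGAGACCACGTTTAGGCGA
50	ai2_23_f	GAGACTGCCGGTGACAAACC	ai2_23_r	AGTTGCAGACTCCAATCCGGA
51	ai2_1244_f	GCCAATACAAACAGTTGCAAAT	ai2_1244_r	TACCAGCTCTCATAGTTTGACG
52	ai2_1125_f	ACCGCTGCAACCCCGCGAGGGT	ai2_1125_r	TGGGCGGCTGCTCCCTTGCGGT
53	ai2_1238_f	GGCACAGGTGGTGCACGGCCGT	ai2_1238_r	GGCATAAGGGGCACGAGTACCT
54	ai2_1166_f	CCGGAGTAATCCGGAGGAAGGT	ai2_1166_r	TGCAATCCGAACTAAGACAAGG
55	ai2_1143_f	TGCCGCCGTGACCGGCGGAGGA	ai2_1143_r	CACTGAGACCACGTTTAGGCGA
56	ai2_1124_f	ACCGCTGCAACCCCGCGAGGGT	ai2_1124_r	AGCGCACCGACTTCTAGTGCAA
57	ai2_1284_f	ACGAGACTGCCTGGGTTAACCA	ai2_1284_r	AGCTTTAAGGATTTGCTCCATC
58	ai2_1288_f	CTGCCTGGGTTAACCAGGAGGA	ai2_1288_r	GAACTGGGGCCAGCTTTAAGGA
59	ai2_1090_f	AAAGGAGACTGCCAGTGATAAA	ai2_1090_r	TCCAATCCGGACTACGACATAC
60	ai2_1142_f	GTGTCGGTAGTTACAGGTGTCT	ai2_1142_r	CAACTCCGCCTTCACGGGGGCG
61	ai2_1195_f	GCGGGTGACCGTATGCTAATCC	ai2_1195_r	CCCTAGGACGATCCTTGCGGTT
62	ai2_101_f	GTCGTCGTCAGCTCGTGCC	ai2_101_r	CTCCTTCCTCCGCCTCGTC
63	ai2_1189_f	CGTCGTAAGATGTGAGGAAGGT	ai2_1189_r	TTCGATCCGAACTGAGAGAGGA
64	ai2_1088_f	CTTATCCTTTGTTGCCAGCGGT	ai2_1088_r	TCCAATCCGGACTACGACATAC
65	ai2_1192_f	GGGGGTACAGAAGGCAGCTAGC	ai2_1192_r	CTTGCGGTTACGTACTTCAGGT
66	ai2_1303_f	GCCATAACGCCGTGAATACGTT	ai2_1303_r	CTTCATCCTAGTCATCAGCCTC
67	ai2_1102_f	AAGTTGGGCAGTCTAAGGTGAC	ai2_1102_r	TCTTGCAGCTCTTTGTACCGTC
68	ai2_54_f	CGGGTGAGTAACACGTATCTAA	ai2_54_r	TCTCAGTTCGGCTACGTATCAT
69	ai2_1275_f	TGATATGGAGCGAATCCCCAAA	ai2_1275_r	GTCTGCCTCCTGCAAGCAGGTT
70	ai2_1327_f	CTGAGCGAATCTCAGAAAGCGC	ai2_1327_r	TTGCCTGGGTTGGGCCACCGGC
71	ai2_10_f	CTGGCGGCGTGGATAAGACA	ai2_10_r	ATGGGCTATTCCCCACTTCAG
72	ai2_1071_f	AGCGATGCCACCCGGCAACGGG	ai2_1071_r	CCTGCCCGTAGGCTCCCGGCGA
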