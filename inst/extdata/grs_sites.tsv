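sequence	strand	start	end	cognate_gene
TTGGTAACGTTTACAC	-	7997	8012	yaaJ/b0007
GTTTAACCGCATTCAC	-	10286	10301	satP/b0010
GCGCAACCGCTACCAC	+	74440	74455	thiP/b0067
GTGGTGGCGCTTACAC	+	74460	74475	thiP/b0067
GTGAACGCCATTACAC	+	103345	103360	ftsQ/b0093
CTGAAAGGGTTTGCAC	+	118258	118273	nadC/b0109
GTGAACTCTTTTCCAC	+	151361	151376	yadK/b0136
TTGCAAATGGTTCCAC	-	151873	151888	yadL/b0137
GTGAAAATGATTGCAC	-	155580	155595	yadV/b0140
GTGGAAAAGTTTCCAC	-	234572	234587	gloB/b0212
GTAGAAACGCCTGCAC	+	329207	329222	betI/b0313
GTGGCATCGTCTTCAC	-	397495	397510	sbmA/0377
GTTTAAGCACTTTCAC	+	684934	684949	gltL/b0652
ATGAAATCGATGCCAC	-	720300	720315	speF/b0693
ATGTAACCGCTACCAC	+	792021	792036	galE/b0759
GTGGAATCGTTTACAC	+	792134	792149	galE/b0759
GTGAAGGCGCTGTCAC	-	863678	863693	fsaA/b0825
GTAAACCCGGTTTCAC	-	957266	957281	ycaP/b0906
GTCAAAACAGTTGCAC	+	1074131	1074146	rutR/b1013
TTGCAACCGTTTTCAC	-	1109176	1109191	opgG/b1048
GTGACATCGCGTCCAC	-	1110864	1113406	opgH/b1049
GAGGAACCGGTAGCAC	-	1156743	1156758	holB/b1099
GTGCAAACGCTATCAG	-	1176651	1176666	lolD/b1117
CTGAAATGGCTTTCAC	+	1413858	1413873	ralR/b1348
CTGCAAGCGCTTGAAC	+	1674225	1674240	tqsA/b1601
GAGCAAACGTTTCCAC	+	1737872	1737887	purR/b1658
ATGGAAGCTTTTCCAC	+	1771431	1771446	ydiM/b1690
GAGTAACCGTCTACAC	-	1791263	1791278	ydiU/b1706
GGGAAAACGATGCCAC	-	1857732	1857747	ydjI/b1773
GTGTCATCGACTGCAC	-	1896369	1896384	nudL/b1813
GTGCAGGAGATTGCAC	+	2005842	2005857	fliT/b1926
ATGGAAACATTTACAC	+	2012342	2012357	yedN/b1932
GTGAAGAGGGTTTCAC	-	2076495	2076510	yeeS/b2002
ATGCAACCGGTTACCC	-	2077222	2077237	cbeA/b2004
GTGTACGCATTTCCAC	+	2108205	2108220	glf/b2036
GTGCACCGGATTTCAC	+	2239532	2239547	mglB/b2150
TTGAAAGCGGTTACAT	+	2240618	2240633	galS/b2151
GGGAAACCGTTGCCAC	+	2241611	2241626	galS/b2151
GCGGAATCGGTTCAAC	+	2278144	2278159	yejG/b2181
GTGCGAACTCTTCCAC	+	2414919	2414934	pta/b2297
CTGCATCCGTTTGCAC	+	2427600	2427615	argT/b2310
CTGCAATCGCCTTCAC	+	2527286	2527301	yfeH/b2410
ATGCAATCGGTTACGC	-	2634124	2634139	guaB/b2508
GTGTACTCTATTACAC	-	2637479	2637494	bamB/b2512
GTAAAGACGATTTCAC	+	2661317	2661332	iscS/b2530
GTGTCGCCGTTTTCAC	+	2796513	2796528	ygaU/b2665
GAGGAAGCGGTTCGAC	+	2817230	2817245	yqaB/b2690
CTGGAAGCGATTGCCC	-	2832047	2832064	norR/b2709
GTGTGAACATTTCCAC	-	2837945	2837960	hydN/b2713
AAGAAACCGGTTTCAC	-	2839425	2839440	ascF/b2715
CTGCAAGCCGTTGCAC	+	2848912	2848927	hycC/b2723
ATGTAAGCGTTTACCC	+	2976569	2976584	galR/b2837
GTTCGACCGCTTTCAC	-	2976830	2976845	galR/b2837
GTTAAAGCATTTACAC	-	2995106	2995121	ygeK/b2856
ATGCAAGTGCTTTCAC	-	3041236	3041251	ygfZ/b2898
CTGAAACCGATTACAC	+	3088004	3088019	galP/b2943
GTGTAAGCGATTACAC	+	3088186	3088201	galP/b2943
GTTGCAGCGATTTCAC	+	3133074	3133089	yghR/b2984
GAGGAAGTGATTGCAC	-	3320107	3320122	yhbX/b3173
CTGGAACCGTATTCAC	+	3372189	3372204	nanT/b3224
GTGGGATCGAGTACAC	-	3375005	3375020	dcuD/b3227
GTAAGAACGGTTACAC	-	3453341	3453356	rpsJ/b3321
AGGAAACCGCTTCCAC	-	3540370	3540385	feoA/b3408
CAGGAAGCGCTTTCAC	-	3552425	3552440	malP/b3417
ATCAAATCGATTACAC	-	3710451	3710466	eptB/b3546
GCGCAACGGCTTCCAC	+	3760922	3760937	selA/b3591
GCGAAATTGATTACAC	+	3824831	3824846	trmH/b3651
GCGCAACCGTTCTCAC	+	3884368	3884383	rpmH/b3703
GGGTAATCGCGTCCAC	-	4256787	4256802	dgkA/b4042
GTGCAAAAGATTGCAC	-	4281671	4281686	yjcE/b4065
GGGTAATCGGTTTTAC	-	4330520	4330535	proP/b4111
GAGAAAACGCTTCAAC	-	4378149	4378164	ampC/b4150
CTGGCATCGTTTACAC	-	4433627	4433642	qorB/b4211
AAGTAAGCGTTTCCAC	-	4449964	4449979	ytfQ/b4227
TTGCCACCGCTTTCAC	-	4483949	4483964	holC/b4259
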