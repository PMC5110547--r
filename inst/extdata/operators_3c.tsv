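seq_id	start	end	strand	name	sequence
NC_000913.3	3088004	3088019	+	galP_OE	CTGAAACCGATTACAC
NC_000913.3	3088186	3088201	+	galP_OI	GTGTAATCGCTTACAC
NC_000913.3	2976569	2976584	+	galR_OE	ATGTAAGCGTTTACCC
NC_000913.3	2976830	2976845	+	galR_OI	GTTCGACCGCTTTCAC
NC_000913.3	2240618	2240633	+	galS_OE	TTGAAAGCGGTTACAT
NC_000913.3	2241611	2241626	+	galS_OI	GGGAAACCGTTGCCAC
NC_000913.3	2239532	2239547	+	mglB_O	GTGCACCGGATTTCAC
NC_000913.3	1737872	1737887	+	F9_O	GTGGAAACGTTTGCTC
NC_000913.3	1990112	1990127	+	F12_O	ATTTAACCGTTTTCTG
NC_000913.3	2246944	2246959	+	F13_O	TTGTTATCGTTTGCAT
NC_000913.3	2738456	2738471	+	F21_O	ATGGAAAAGGTTGCAC
NC_000913.3	2783816	2783831	+	F22-1_O	GCGAAAACGGTTTAAG
NC_000913.3	2784177	2784192	+	F22-2_O	CTGCAAGCTTTTTCCA
NC_000913.3	2786317	2786332	+	F22-3_O	TTGCAATTACTTTCAC
NC_000913.3	3072949	3072964	+	F25-1_O	CTTAAATCGATTGCCG
NC_000913.3	3072989	3073004	+	F25-2_O	TTTGAAGCGATTGCGG
NC_000913.3	3073430	3073445	+	F25-3_O	CTGCAATCGCTCCCCT
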