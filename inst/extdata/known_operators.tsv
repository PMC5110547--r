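seq_id	start	end	strand	name	sequence
NC_000913.3	792021	792036	+	galE_OE	ATGTAACCGCTACCAC
NC_000913.3	792134	792149	+	galE_OI	GTGGAATCGTTTACAC
NC_000913.3	3088004	3088019	+	galP_OE	CTGAAACCGATTACAC
NC_000913.3	3088186	3088201	+	galP_OI	GTGTAATCGCTTACAC
NC_000913.3	2976569	2976584	+	galR_OE	ATGTAAGCGTTTACCC
NC_000913.3	2976830	2976845	-	galR_OI	GTTCGACCGCTTTCAC
NC_000913.3	2240618	2240633	+	galS_OE	TTGAAAGCGGTTACAT
NC_000913.3	2241611	2241626	+	galS_OI	GGGAAACCGTTGCCAC
NC_000913.3	2239532	2239547	+	mglB_O	GTGCACCGGATTTCAC
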