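peak_position	peak_score	genes	inferred_site
8005	15.4	yaaJ/talB	TTGGTAACGTTTACA
708069	4.9	chiP	ATGAAAGCGGTTACA
767563	4.5	(mngA)	GTGGAAGCGGTTACG
792029	78.1	galE	GTGGTAGCGGTTACA
792441	NA	NA	GTGGAATCGTTTACA
1627951	3.9	(ydfG)	GTGGTAACGTTTACG
1737880	9.5	ynhF/purR	GTGGAAACGTTTGCT
1737791	NA	NA	AGGCAAACGTTTACC
2240625	9.5	mglB	TTGAAAGCGGTTACA
2241771	10.9	galS	ATGGAAACGGTTACA
2241619	NA	NA	GTGGCAACGGTTTCC
2976577	21.2	omrB/galR	GGGTAAACGCTTACA
3088194	115.4	galP	GTGTAATCGCTTACA
3532886	4.6	yhgE/pck	ATGATATCGTTTACA
3991055	12.4	hemC/cyaA	GTGGTAACGGTTACC
4124542	3.5	cytR	GTGAAAACGGTTACA
4338179	6.9	adiY	ATGGCAACGTTTTCA
4338257	NA	NA	GTGGTTACGCTTTCA
4449971	22	ppa/ytfQ	GTGGAAACGCTTACT
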