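coordinate	bits	cognate_gene
37821	10.03857	caiC
43400	9.814199	fixB
74447	11.21879	thiQ-thiB
89735	11.40643	mraZ
103352	9.751084	ftsQ
161073	9.635808	sfsA
167231	9.801062	mrcB
234579	10.76336	gloB
306553	10.13984	ecpE-ecpC
390979	9.664174	NA
741888	11.21261	dtpD
787535	12.30803	gpmA
791362	10.91125	galE
792028	20.50652	galE
792141	19.60408	galE-modF
914977	9.870273	ybjE-aqpZ
986589	10.22057	ompF
1109183	10.44796	opgC-opgG
1191794	9.613439	purB
1253804	9.870957	ycgV
1307943	10.76489	clsA
1347064	9.781962	rnb
1353246	10.53007	sapD
1466984	9.647879	NA
1539818	12.88323	narY-narU
1572923	11.06094	pqqL
1712019	10.58487	rsxE-dtpA
1798963	9.813867	pheS-pheM
1803105	9.629957	NA
1857739	13.26586	ydjI
1958198	11.84791	torY-cutC
2012349	10.87027	NA
2076502	11.88679	yeeR-yeeT
2188111	11.89384	yehA
2239539	11.87394	mglB
2240625	13.75395	mglB-galS
2241618	9.470329	galS
2241771	10.95166	galS-yeiB
2390045	11.86583	yfbP-nuoN
2585453	9.76911	aegA
2738463	10.28531	pheA
2751444	11.95696	nadK
2783823	12.3442	ypjC
2839356	12.65853	ascG-ascF
2976576	16.03935	omrB-galR
2976837	14.07919	galR
3069624	11.39436	mscS
3088011	14.78781	metK-galP
3088193	25.1484	metK-galP
3115470	9.845925	sslE
3236977	10.89744	ygjQ
3287545	12.34189	yraH
3288641	10.85878	yraI
3492468	9.731226	ppiA-tsgA
3656067	10.56542	hdeB
3665637	9.573374	gadX
3700787	10.21665	yhjV
4124542	13.28446	cytR-priA
4155030	10.04465	argC
4573916	11.67178	NA
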