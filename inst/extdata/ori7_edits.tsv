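origin	replacement_label	chrom	start	end	replacement_length
ARS600	LEU2	chrVI	5435	20826	2230
ARS601/2	loxP	chrVI	32473	33247	34
ARS603	loxP	chrVI	68693	68871	34
ARS603.5	KanMX	chrVI	118637	118957	1400
ARS604	loxP	chrVI	127751	128071	34
ARS605	loxP	chrVI	135985	136085	34
ARS606	ADE2	chrVI	167614	168048	2280
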