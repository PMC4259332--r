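chrVI	5434	20826	ARS600	0	.
chrVI	32472	33247	ARS601/2	0	.
chrVI	54999	55300	ARS602.5	0	.
chrVI	68692	68871	ARS603	0	.
chrVI	96999	97300	ARS603.1	0	.
chrVI	118636	118957	ARS603.5	0	.
chrVI	127750	128071	ARS604	0	.
chrVI	135984	136085	ARS605	0	.
chrVI	167613	168048	ARS606	0	.
chrVI	199299	199600	ARS607	0	.
chrVI	216699	217000	ARS608	0	.
chrVI	254999	255300	ARS609	0	.
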