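chrIII	183999	192000	.	0	.
chrVI	79999	86000	.	0	.
chrXII	844999	870000	.	0	.
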