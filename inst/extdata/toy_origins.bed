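toy	49899	50100	ORI_A	0	.
toy	149899	150100	ORI_B	0	.
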