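Proteases	A	AE	W	B	V
Tryptic	0.0250	0.0000	0.0000	0.0020	0.0000
PostC	0.0250	0.0000	0.0000	0.0020	0.0000
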