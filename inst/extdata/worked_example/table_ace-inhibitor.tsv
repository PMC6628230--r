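Proteases	A	AE	W	B	V
Tryptic	0.1000	0.0500	0.5000	0.0300	0.8333
PostC	0.1000	0.0000	0.0000	0.0300	0.0000
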