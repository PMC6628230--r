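Proteases	DHt
Tryptic	15.3846
PostC	0.0000
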