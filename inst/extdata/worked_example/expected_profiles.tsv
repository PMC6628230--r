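protein_id	activity	enzyme	n_residues	a	d	A	A_E	W	B	B_E	V	dh_t	calculable
toy40	ace inhibitor	Tryptic	40	4	2	0.1	0.05	0.5	0.03	0.025	0.8333333333333334	15.384615384615385	TRUE
toy40	ace inhibitor	PostC	40	4	0	0.1	0	0	0.03	0	0	0	TRUE
toy40	dipeptidyl peptidase iv inhibitor	Tryptic	40	6	0	0.15	0	0	0	0	NA	15.384615384615385	TRUE
toy40	dipeptidyl peptidase iv inhibitor	PostC	40	6	0	0.15	0	0	0	0	NA	0	TRUE
toy40	antioxidative	Tryptic	40	1	0	0.025	0	0	0.002	0	0	15.384615384615385	TRUE
toy40	antioxidative	PostC	40	1	0	0.025	0	0	0.002	0	0	0	TRUE
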