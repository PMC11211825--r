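smiles	sequence	label
CCO	MKVLAAGICWNQHLL	1
CCN	MKVLAAGICWNQHLL	0
c1ccncc1	ACDEFGHIKLMNPQRSTVWY	1
CCCl	ACDEFGHIKLMNPQRSTVWY	0
CC(=O)O	MKVLAAGICWNQHLL	0
CCCO	ACDEFGHIKLMNPQRSTVWY	0
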