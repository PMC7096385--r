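id	name	chebi
L1	C18:1 n-9	CHEBI:36021
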