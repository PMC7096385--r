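source	kind	target
CHEBI:16196	IS_A	CHEBI:36021
CHEBI:36021	IS_A	CHEBI:25413
CHEBI:25413	IS_A	CHEBI:27208
CHEBI:27208	IS_A	CHEBI:35366
CHEBI:15756	IS_A	CHEBI:35366
CHEBI:30823	CONJUGATE_BASE_OF	CHEBI:16196
CHEBI:28868	CONJUGATE_BASE_OF	CHEBI:35366
CHEBI:7896	CONJUGATE_BASE_OF	CHEBI:15756
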