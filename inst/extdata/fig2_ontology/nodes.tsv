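id	name	synonyms	is_obsolete
CHEBI:36021	octadec-9-enoic acid		false
CHEBI:16196	oleic acid	octadec-9Z-enoic acid	false
CHEBI:30823	oleate		false
CHEBI:25413	octadecenoic acid		false
CHEBI:27208	unsaturated fatty acid		false
CHEBI:35366	fatty acid		false
CHEBI:28868	fatty acid anion		false
CHEBI:15756	hexadecanoic acid		false
CHEBI:7896	hexadecanoate		false
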