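upstream_gene	downstream_gene
BRAF	MAP2K1
MAP2K1	MAPK3
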