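context_gene	context_alteration	dependent_gene
BRAF	ONCOGENIC_SNV	MAP2K1
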