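gene	variant_key	function_effect	zygosity_required	affected_drugs	label
DPYD	1:97915614:C:T	DECREASED	HET	D_FU,D_CAPE	MODERATELY_RECOMMENDED
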