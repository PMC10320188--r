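drug_id	gene	association_type	response	n_sources	required_alteration
D_VEMU	BRAF	DIRECT_TARGET	SENSITIVITY	5	ONCOGENIC_SNV
D_VEMU	MAP2K1	BIOMARKER	SENSITIVITY	3	SNV
D_TRAM	MAP2K1	DIRECT_TARGET	SENSITIVITY	5	ANY
D_TRAM	MAP2K1	BIOMARKER	SENSITIVITY	2	SNV
D_TRAM	BRAF	BIOMARKER	SENSITIVITY	4	ONCOGENIC_SNV
D_TRAM	CDKN2A	BIOMARKER	SENSITIVITY	2	DEL
D_TRAM	G6PD	BIOMARKER	SENSITIVITY	1	ANY
D_EVER	MTOR	DIRECT_TARGET	SENSITIVITY	4	ONCOGENIC_SNV
D_SIRO	MTOR	DIRECT_TARGET	SENSITIVITY	3	ONCOGENIC_SNV
D_ALPE	PIK3CA	DIRECT_TARGET	SENSITIVITY	5	ONCOGENIC_SNV
D_ALPE_FULV	PIK3CA	DIRECT_TARGET	SENSITIVITY	3	ONCOGENIC_SNV
D_CAPE	TP53	BIOMARKER	SENSITIVITY	3	ANY
D_GEMC	TP53	BIOMARKER	SENSITIVITY	3	ANY
D_DOCE	TP53	BIOMARKER	SENSITIVITY	3	ANY
D_FU	TP53	BIOMARKER	SENSITIVITY	2	ANY
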