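gene	driver_role	essentiality	clinical_level	clinical_cancer_types
BRAF	ONCOGENE	0.9	APPROVED_BIOMARKER	SKIN
MAP2K1	ONCOGENE	0.8	APPROVED_BIOMARKER	SKIN
CDKN2A	TSG	0.5	LATE_TRIALS	SKIN
G6PD	NONE	0.3	EARLY_TRIALS	
MTOR	ONCOGENE	0.7	APPROVED_BIOMARKER	BREAST,KIDNEY
PIK3CA	ONCOGENE	0.85	APPROVED_BIOMARKER	BREAST
TP53	TSG	0.6	LATE_TRIALS	PAN_CANCER
DPYD	NONE	0.1	NONE	
MAPK3	NONE	0.4	NONE	
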