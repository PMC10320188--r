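# version=curated-fixture-1.0
drug_id	name	family	clinical_status	indications	therapy_type
D_VEMU	VEMURAFENIB	RAF inhibitor	APPROVED	SKIN	TARGETED
D_TRAM	TRAMETINIB	MEK inhibitor	APPROVED	SKIN	TARGETED
D_EVER	EVEROLIMUS	MTOR inhibitor	APPROVED	BREAST,KIDNEY	TARGETED
D_SIRO	SIROLIMUS	MTOR inhibitor	APPROVED	KIDNEY	TARGETED
D_ALPE	ALPELISIB	PI3K inhibitor	APPROVED	BREAST	TARGETED
D_ALPE_FULV	ALPELISIB + FULVESTRANT	PI3K inhibitor + ER antagonist	APPROVED	BREAST	TARGETED
D_CAPE	CAPECITABINE	Fluoropyrimidine	APPROVED	BREAST,COLON	CHEMOTHERAPY
D_GEMC	GEMCITABINE	Nucleoside analogue	APPROVED	BREAST,LUNG	CHEMOTHERAPY
D_DOCE	DOCETAXEL	Taxane	APPROVED	BREAST,PROSTATE	CHEMOTHERAPY
D_FU	FLUOROURACIL	Fluoropyrimidine	APPROVED	BREAST,COLON	CHEMOTHERAPY
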