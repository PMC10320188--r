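##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Annotated gene symbol">
##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description="Variant consequence term">
##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description="Predicted deleterious">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
3	178936091	.	G	A	.	PASS	GENE=PIK3CA;CONSEQUENCE=missense;DELETERIOUS	GT:AD	0/1:40,60
17	7577120	.	C	T	.	PASS	GENE=TP53;CONSEQUENCE=missense;DELETERIOUS	GT:AD	0/1:52,48
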