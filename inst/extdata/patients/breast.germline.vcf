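##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Annotated gene symbol">
##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description="Variant consequence term">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NORMAL
1	97915614	.	C	T	.	PASS	GENE=DPYD;CONSEQUENCE=splice	GT:AD	0/1:30,28
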