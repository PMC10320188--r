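##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Annotated gene symbol">
##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description="Variant consequence term">
##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description="Predicted deleterious">
##INFO=<ID=POPAF,Number=1,Type=Float,Description="Population allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
7	140453136	.	A	T	.	PASS	GENE=BRAF;CONSEQUENCE=missense;DELETERIOUS	GT:AD	0/1:60,40
15	66727455	.	G	A	.	PASS	GENE=MAP2K1;CONSEQUENCE=missense;DELETERIOUS	GT:AD	0/1:50,50
X	153762634	.	C	T	.	PASS	GENE=G6PD;CONSEQUENCE=missense;DELETERIOUS	GT:AD	0/1:55,45
1	11205058	.	C	T	.	PASS	GENE=MTOR;CONSEQUENCE=missense;DELETERIOUS	GT:AD	0/1:48,52
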