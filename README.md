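# drugrank

Multi-omics drug prioritization for precision oncology, as an R package
with a command-line workflow.

Tumor sequencing leaves researchers and clinicians with long lists of
molecular alterations, most of them unactionable. `drugrank` integrates a
patient's somatic and germline small variants (VCF), gene-level
copy-number calls (TSV), and expression ranking (RNK) — or a bare gene
list — against a drug–gene knowledge base, and returns a ranked,
evidence-annotated list of candidate therapies.

## The scores

For each altered gene $g$ it computes an actionability **GScore**
$\in [0,1]$:

$$\mathrm{GScore}(g) = \min\Big(1, \sum_i w_i c_i + b\Big)$$

over five components $c_i$ — alteration consequence impact, population
rarity, cancer essentiality, druggability, clinical implication — plus a
multi-omics concordance bonus $b$. For each drug–gene association it
computes a suitability **DScore** $\in [-1,1]$ whose magnitude weighs
clinical status, indication match, association class (direct target,
biomarker, genetic dependency, pathway member), curation support and the
collective gene impact $1 - \prod_i (1 - g_i/2)$, and whose sign is
positive for sensitivity and negative for resistance evidence. Rows with
GScore > 0.6 and DScore > 0.7 (strict) are flagged **Best Therapeutic
Candidates** (BTCs) and listed in a two-section genomic report; a
CPIC-style rules engine annotates drugs affected by germline
pharmacogenetic variants (e.g. DPYD-guided fluoropyrimidine caution).

Genetic-dependency and pathway-member expansion propose surrogate targets
for untargetable alterations; *clinical* vs *discovery* query modes
restrict or widen the evidence admitted. See
`vignettes/drug-prioritization.Rmd` for the full model.

## Worked example

A bundled BRAF-mutant melanoma profile against the curated knowledge-base
fixture:

```r
library(drugrank)
kb <- load_knowledge_base(system.file("extdata", "kb_curated",
                                      package = "drugrank"))
profile <- build_profile(
  somatic = parse_vcf(system.file("extdata", "patients",
                                  "melanoma.somatic.vcf",
                                  package = "drugrank"), "SOMATIC"),
  cnv  = parse_cnv_tsv(system.file("extdata", "patients",
                                   "melanoma.cnv.tsv",
                                   package = "drugrank")),
  expr = parse_rnk(system.file("extdata", "patients", "melanoma.rnk",
                               package = "drugrank")),
  cancer_type = "SKIN", mode = "CLINICAL")
res <- run_query(profile, kb)
res$table[, c("rank", "drug_name", "gene", "evidence_class",
              "gscore", "dscore", "is_btc")]
```

prints:

```
  rank   drug_name   gene     evidence_class  gscore    dscore is_btc
1    1  TRAMETINIB MAP2K1      DIRECT_TARGET 1.00000 0.9856927   TRUE
2    2 VEMURAFENIB   BRAF      DIRECT_TARGET 0.93500 0.9600625   TRUE
3    3  TRAMETINIB   BRAF          BIOMARKER 0.93500 0.9456927   TRUE
4    4  TRAMETINIB MAP2K1 GENETIC_DEPENDENCY 0.84150 0.9256927   TRUE
5    5  TRAMETINIB MAP2K1          BIOMARKER 1.00000 0.9056927   TRUE
6    6  TRAMETINIB CDKN2A          BIOMARKER 0.87500 0.9056927   TRUE
7    7 VEMURAFENIB MAP2K1          BIOMARKER 1.00000 0.9000625   TRUE
8    8  TRAMETINIB   G6PD          BIOMARKER 0.72625 0.8856927   TRUE
```

The RAF inhibitor vemurafenib is a BTC because it directly targets the
oncogenic BRAF mutation (GScore 0.935: deleterious missense in an approved
skin biomarker that is also a direct drug target); the MEK inhibitor
trametinib is additionally supported by a MAP2K1 genetic dependency in
BRAF-mutant context, the CDKN2A deletion biomarker and G6PD overexpression.
Re-running with `options = list(cancer_type = "ALL")` adds the MTOR
inhibitors everolimus and sirolimus as repurposing candidates driven by
the MTOR oncogenic mutation.

The same workflow is available from a shell:

```sh
Rscript inst/cli/drugrank.R query-multiomics \
  --kb inst/extdata/kb_curated \
  --vcf-somatic inst/extdata/patients/melanoma.somatic.vcf \
  --cnv inst/extdata/patients/melanoma.cnv.tsv \
  --rnk inst/extdata/patients/melanoma.rnk \
  --cancer-type SKIN --mode clinical --out out/
```

writing `results.tsv`, `report.md`, `report.json`, `pgx_report.json` and
`run.log`.

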