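---
title: "Scoring and prioritizing therapies from multi-omics tumor profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and prioritizing therapies from multi-omics tumor profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrank)
```

## The problem

Tumor sequencing confronts the analyst with long lists of somatic variants,
copy-number changes and deregulated genes, most of which are not clinically
actionable. `drugrank` turns such a multi-omics profile into a ranked,
evidence-annotated list of candidate therapies by combining two scores
against a drug–gene knowledge base:

* **GScore** — per-gene actionability in $[0, 1]$. It aggregates the
  biological impact of the gene's alterations, the rarity of the variant in
  the population, the gene's essentiality in cancer cell lines, its
  druggability, and the clinical implication of the gene as a biomarker.
* **DScore** — per-drug suitability in $[-1, 1]$. Its magnitude combines
  the drug's clinical status, indication match with the queried tumor type,
  the class of the drug–gene association, the number of curated sources
  supporting it, and the *collective gene impact* of the drug; its sign is
  positive for sensitivity evidence and negative for resistance.

Rows with GScore $> 0.6$ **and** DScore $> 0.7$ (both strict) are flagged
**Best Therapeutic Candidates** (BTCs) and surfaced in the two-section
genomic report.

## The model

### Gene actionability

For gene $g$ with component scores $c_i \in [0,1]$,

$$\mathrm{GScore}(g) = \min\!\Big(1,\; \sum_i w_i c_i + b\Big),$$

with default weights $w = (0.25, 0.10, 0.15, 0.25, 0.25)$ for consequence,
frequency, essentiality, druggability and clinical components, and a
concordance bonus $b \in \{0, 0.1, 0.2\}$. Choices worth making explicit:

* **Per-alteration aggregation is max, not sum.** A gene is as actionable
  as its strongest alteration; summing would let many weak alterations
  mimic one strong driver.
* **Consequence impacts** come from a fixed table (truncating = 1.0,
  predicted-deleterious missense = 0.8, plain missense = 0.5, in-frame
  indel = 0.6, synonymous/other = 0). Truncating events in a pure oncogene
  are halved — loss of function rarely activates an oncogene. Non-variant
  alterations map onto the same scale (driver-concordant CNV 0.9,
  discordant 0.4; driver-concordant extreme expression 0.7, discordant
  0.2; gene-list entries 0.8, since a bare gene query asserts the gene is
  actionably altered). Variants with VAF below 0.05 are treated as
  subclonal and down-weighted by 0.8.
* **Frequency term**: 1 at or below a population allele frequency of
  1e-4 (or when unknown — rare by default), 0 at or above 1e-2,
  log-linear in between. It is taken from the highest-impact somatic
  variant, so a common benign passenger cannot mask a rare driver.
* **Druggability ladder**: direct target 1.0 > biomarker 0.75 > dependent
  gene of a genetic-dependency pair 0.5 > druggable downstream pathway
  member 0.25 > none 0.
* **Clinical ladder**: approved biomarker 1.0 down to none 0, with a 0.75
  multiplicative penalty when the gene's clinical evidence comes from a
  different tumor type than the one queried (pan-cancer evidence never
  penalized).
* **Concordance bonus**: +0.1 for two and +0.2 for three altered channels
  (mutation / copy number / expression) pushing the same driver direction
  — activation (amplification, overexpression) for oncogenes, loss
  (deletion, underexpression) for tumor suppressors; small variants are
  direction-neutral. Conflicting directions forfeit the bonus.
* **Cap-at-1 instead of renormalizing** keeps every component
  interpretable on its own scale; the bonus can only push a gene across
  ranking boundaries, never out of range.

### Drug suitability

$$\mathrm{DScore}(d) = s \cdot \sum_j v_j k_j, \qquad s = \begin{cases}+1 &
\text{sensitivity}\\ -1 & \text{resistance}\end{cases}$$

with default weights $v = (0.35, 0.20, 0.20, 0.10, 0.15)$ for status,
indication, association class, curation support and collective impact.
Status: approved 1.0, clinical trials 0.6, experimental 0.2. Indication:
queried cancer type 1.0, another cancer 0.5 (repurposing), non-cancer
0.25; querying `ALL` accepts any cancer indication. Association class:
direct target 1.0, biomarker 0.9, genetic dependency 0.7, pathway member
0.5. Support saturates linearly at five curated sources. The collective
gene impact is a noisy-OR over the GScores $g_i$ of the queried druggable
genes linked to the drug:

$$\mathrm{collective} = 1 - \prod_i \Big(1 - \frac{g_i}{2}\Big) \in [0, 1),$$

which strictly rewards each additional positively scored target with
diminishing returns — the drug able to hit the most druggable genes in the
query wins, without a handful of targets saturating the term.

Conflicting evidence (a sensitivity association on one gene, resistance on
another) produces two signed rows rather than a netted score; vetoing is
left to the reader, who sees both.

### Evidence expansion

Altered genes are classified as **direct targets** or **biomarkers** when
an association's required-alteration pattern matches the observed
alterations. The matching grammar uses the tokens `SNV`, `ONCOGENIC_SNV`
(a variant whose consequence impact is at least 0.8), `AMP`, `DEL`,
`OVEREXPR`, `UNDEREXPR` and `ANY`; gene-list entries match every pattern.
Two expansions then extend the therapeutic options to untargetable genes:

* **Genetic dependencies** — when a dependency pair's context gene and
  alteration match the profile, the dependent gene is emitted with the
  direct-target drugs of the dependent gene, inheriting the context gene's
  GScore times 0.9 (the vulnerability is one experimental inference away
  from the observed alteration).
* **Pathway members** — a breadth-first walk (default depth 3, cycles cut
  by a visited set) down directed pathway edges; each reached druggable
  gene inherits the origin GScore times $0.75^{\text{depth}}$, so indirect
  evidence decays geometrically with distance.

### Query modes

*Clinical* mode restricts output to drugs that are approved or in clinical
trials, with direct-target / biomarker / genetic-dependency evidence, and
**indicated for the queried cancer type**. The last gate is a deliberate
design choice: repurposing candidates (drugs approved for other tumor
types) only enter when the user widens the search to `ALL` cancer types or
switches to *discovery* mode, which keeps everything, including
experimental drugs and pathway-member evidence. This makes "expanding the
drug search to other cancer types" an explicit query action rather than a
silent default, and guarantees the clinical result is always a subset of
the discovery result. Germline variants never generate therapy rows; they
feed the pharmacogenetic rules engine, whose labels annotate (and never
re-rank) the table.

### Pharmacogenetics

A deliberately simplified CPIC-style engine: single-variant keys
(`chrom:pos:ref:alt`) plus a zygosity requirement, in place of full
star-allele diplotype calling. A homozygous call satisfies a heterozygous
requirement; conflicting rules resolve to the most severe label
(strongly-not-recommended > moderately-recommended > standard). This
suffices for deterministic desk-scale behaviour such as DPYD-guided
fluoropyrimidine caution; the rule schema keeps a variant-key field that
can hold star-allele tags for future extension. Phasing, haplotype
inference and dosing arithmetic are out of scope.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `gscore$weights` | 0.25/0.10/0.15/0.25/0.25 | emphasize druggability and clinical evidence, which gate real-world actionability |
| `dscore$weights` | 0.35/0.20/0.20/0.10/0.15 | clinical status dominates: an approved drug with modest evidence beats an experimental one with perfect evidence |
| BTC thresholds | GScore > 0.6, DScore > 0.7 | published definition; strict inequalities, so boundary rows are never flagged |
| expression cutoffs | ≥ 0.90 / ≤ 0.10 percentile | decile tails of the supplied ranking; the ranking itself carries no natural units |
| subclonal VAF | < 0.05, ×0.8 | a near-absent clone is weaker evidence for prescribing |
| support saturation | 5 sources | beyond a handful of independent curated sources, additional listings add little |
| pathway depth / decay | 3 hops, 0.75 per hop | indirect evidence beyond three steps is too diluted to act on |
| dependency decay | 0.9 | one well-controlled screen result is nearly as strong as direct alteration |

Every value is overridable through a YAML file passed to `load_config()`
(CLI flag `--config`).

## The synthetic knowledge base

No public drug–gene database ships with the package; testing runs entirely
against synthetic instances from `generate_fixture_kb()`. The generator
emulates the *shape* of a curated pharmacogenomic database — uniqueness
and referential integrity across six tables, realistic enum frequencies
(40% approved drugs, ~15% resistance associations, 1–8 supporting
sources), sparse dependency and pathway graphs — and, with
`curated = TRUE`, embeds two hand-written clinical scenarios: a BRAF-mutant
melanoma case (RAF/MEK inhibitors, a MAP2K1 dependency in BRAF-mutant
context, a CDKN2A deletion biomarker, MTOR inhibitors indicated elsewhere)
and a PIK3CA-mutant breast case (alpelisib alone and combined with
fulvestrant, approved chemotherapies, a heterozygous DPYD rule labelling
the fluoropyrimidines). Default random scale is 50 genes / 30 drugs: large
enough for ranking ties, small enough for exhaustive oracles.

What the generator does **not** emulate: real mutation spectra and allele
frequencies, correlated omics channels, genome coordinates tied to an
assembly, the long-tailed source-count distribution of real curation, or
drug ontology beyond a free-text family string. Passing tests therefore
demonstrate the correctness and invariants of the scoring machinery, not
clinical validity on real cohorts.

## Numerical and degenerate-input choices

* Weights must sum to 1 within 1e-9; violations are configuration errors,
  not silent renormalizations.
* Ties in ranking break by per-row GScore, then normalized drug name, so
  output files are reproducible byte for byte.
* Duplicate CNV rows keep the last status (with a warning); duplicate RNK
  rows keep the most extreme absolute value (a signed ranking's
  informative end).
* Unknown genes score 0 for essentiality, druggability and clinical
  components but still surface if an association matches.
* Empty queries fail fast with a classed error; an empty knowledge base is
  valid and round-trips through write/load.
* All randomness (fixtures only — the pipeline itself is deterministic)
  flows through explicit integer seeds.

## Problem sizes used in the shipped checks

The property suites use 10,000 randomized component draws per engine, 100
random end-to-end prioritization runs (40-gene / 25-drug knowledge bases,
8 altered genes each) for the BTC threshold sweep, and 100 random
fixtures for the clinical-subset law; the curated scenarios run in
milliseconds. These sizes give stable extrema across seeds while keeping
a full run of the suite around a minute on one core.

## Worked example

```{r example}
kb <- load_knowledge_base(system.file("extdata", "kb_curated",
                                      package = "drugrank"))
profile <- build_profile(
  somatic = parse_vcf(system.file("extdata", "patients",
                                  "melanoma.somatic.vcf",
                                  package = "drugrank"), "SOMATIC"),
  cnv = parse_cnv_tsv(system.file("extdata", "patients", "melanoma.cnv.tsv",
                                  package = "drugrank")),
  expr = parse_rnk(system.file("extdata", "patients", "melanoma.rnk",
                               package = "drugrank")),
  cancer_type = "SKIN", mode = "CLINICAL")
result <- run_query(profile, kb)
result$table[, c("rank", "drug_name", "gene", "evidence_class",
                 "gscore", "dscore", "is_btc")]
```

Re-running with `options = list(cancer_type = "ALL")` widens the search
and surfaces the MTOR inhibitors as repurposing candidates.

## Known limitations

* The numeric ladders and weights are this package's documented defaults;
  the methodology's published description names the score ingredients and
  ranges but not the constants, so absolute score values are not
  comparable across implementations — rankings and the score *laws*
  (ranges, sign, thresholds, monotonicity) are the tested contract.
* Variant annotation is consumed, not computed: unannotated VCFs yield
  records without gene/consequence and are dropped from scoring with a
  warning.
* Single-variant pharmacogenetic rules cannot represent compound
  heterozygosity or structural star alleles.
* No dose modelling, drug–drug interactions, or resistance anticipation.
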