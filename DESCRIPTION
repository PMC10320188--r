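Package: drugrank
Title: Multi-Omics Drug Prioritization for Precision Oncology
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates a patient's somatic and germline small variants,
    gene-level copy-number status and expression ranking against a bundled
    drug-gene knowledge base to score gene actionability (GScore, in [0,1])
    and drug suitability (DScore, in [-1,1]), classify druggability evidence
    (direct target, biomarker, genetic dependency, pathway member), select
    Best Therapeutic Candidates, annotate germline pharmacogenetic
    recommendations, and emit a two-section clinical decision report. Ships a
    seeded synthetic knowledge-base generator and curated desk-scale fixtures
    for reproducible testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
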