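test_that("evidence classification matches required-alteration patterns", {
  kb <- curated_kb()
  prof <- melanoma_profile()
  braf <- classify_evidence("BRAF", prof, kb)
  expect_true(any(braf$evidence_class == "DIRECT_TARGET" &
                    braf$drug_id == "D_VEMU"))
  map2k1 <- classify_evidence("MAP2K1", prof, kb)
  expect_true(any(map2k1$evidence_class == "BIOMARKER" &
                    map2k1$drug_id == "D_TRAM"))
  # CDKN2A deletion satisfies the DEL-gated biomarker
  cdkn2a <- classify_evidence("CDKN2A", prof, kb)
  expect_true(any(cdkn2a$drug_id == "D_TRAM"))
  # an unaltered (neutral-expression) gene yields nothing
  expect_equal(nrow(classify_evidence("FILLER09", prof, kb)), 0)
})

test_that("dependency expansion emits dependent-gene direct-target drugs", {
  kb <- curated_kb()
  prof <- melanoma_profile()
  gs <- data.frame(gene = "BRAF", gscore = 0.935, stringsAsFactors = FALSE)
  dep <- expand_dependencies(prof, kb, gs)
  expect_equal(dep$gene, "MAP2K1")
  expect_equal(dep$evidence_class, "GENETIC_DEPENDENCY")
  expect_equal(dep$drug_id, "D_TRAM")
  expect_equal(dep$gscore, 0.935 * 0.9)

  # no context match, no emissions
  prof2 <- build_profile(genes = "CDKN2A", cancer_type = "SKIN")
  gs2 <- data.frame(gene = "CDKN2A", gscore = 0.8, stringsAsFactors = FALSE)
  expect_equal(nrow(expand_dependencies(prof2, kb, gs2)), 0)

  # two pairs to the same dependent gene merge into one emission
  kb2 <- kb
  kb2$dependencies <- rbind(kb$dependencies,
                            data.frame(context_gene = "G6PD",
                                       context_alteration = "SNV",
                                       dependent_gene = "MAP2K1",
                                       stringsAsFactors = FALSE))
  gs3 <- data.frame(gene = c("BRAF", "G6PD"), gscore = c(0.935, 0.7),
                    stringsAsFactors = FALSE)
  dep2 <- expand_dependencies(prof, kb2, gs3)
  expect_equal(nrow(dep2), 1)
  expect_equal(dep2$gscore, 0.935 * 0.9)  # best inherited score survives
})

test_that("pathway expansion decays per hop and survives cycles", {
  ann <- data.frame(gene = c("A", "B", "C"), driver_role = "NONE",
                    essentiality = 0.5, clinical_level = "NONE",
                    clinical_cancer_types = "", stringsAsFactors = FALSE)
  drugs <- data.frame(drug_id = "D1", name = "DRUG ONE", family = "x",
                      clinical_status = "APPROVED", indications = "SKIN",
                      therapy_type = "TARGETED", stringsAsFactors = FALSE)
  assoc <- data.frame(drug_id = "D1", gene = "C",
                      association_type = "DIRECT_TARGET",
                      response = "SENSITIVITY", n_sources = 2L,
                      required_alteration = "ANY", stringsAsFactors = FALSE)
  edges <- data.frame(upstream_gene = c("A", "B", "B"),
                      downstream_gene = c("B", "C", "A"),
                      stringsAsFactors = FALSE)
  kb <- knowledge_base(drugs = drugs, associations = assoc,
                       gene_annotations = ann, pathway_edges = edges)
  prof <- build_profile(genes = "A", cancer_type = "SKIN")
  gs <- data.frame(gene = "A", gscore = 1.0, stringsAsFactors = FALSE)
  pm <- expand_pathway(prof, kb, gs, max_depth = 2)
  expect_equal(nrow(pm), 1)  # cycle A->B->A terminates, no duplicates
  expect_equal(pm$gene, "C")
  expect_equal(pm$gscore, 0.75^2)
  # depth 1 cannot reach C
  expect_equal(nrow(expand_pathway(prof, kb, gs, max_depth = 1)), 0)
  expect_error(expand_pathway(prof, kb, gs, max_depth = 0),
               class = "drugrank_argument_error")
})

test_that("clinical mode filters status, evidence class and indication", {
  rows <- data.frame(
    drug_id = c("D1", "D2", "D3", "D4"),
    clinical_status = c("APPROVED", "EXPERIMENTAL", "APPROVED",
                        "CLINICAL_TRIAL"),
    evidence_class = c("DIRECT_TARGET", "DIRECT_TARGET", "PATHWAY_MEMBER",
                       "GENETIC_DEPENDENCY"),
    indication_component = c(1, 1, 1, 0.5),
    stringsAsFactors = FALSE)
  kept <- apply_mode(rows, list(mode = "CLINICAL"))
  expect_equal(kept$drug_id, "D1")
  expect_equal(apply_mode(rows, list(mode = "DISCOVERY")), rows)
  expect_equal(nrow(apply_mode(rows[0, ], list(mode = "CLINICAL"))), 0)
})

test_that("ranking sorts by dscore, gscore, name; BTC thresholds strict", {
  rows <- data.frame(
    drug_id = c("A", "B", "C", "D"),
    drug_name = c("ZETA", "ALPHA", "MID", "MID2"),
    gene = "G",
    gscore = c(0.8, 0.6, 0.9, 0.5),
    dscore = c(0.9, 0.9, 0.9, 0.701),
    stringsAsFactors = FALSE)
  out <- rank_and_select(rows)
  # equal dscore: higher gscore first; then name breaks the 0.8-tie group
  expect_equal(out$rows$drug_name, c("MID", "ZETA", "ALPHA", "MID2"))
  expect_equal(out$rows$is_btc, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$btc$drug_name, c("MID", "ZETA"))

  boundary <- data.frame(drug_id = "X", drug_name = "X", gene = "G",
                         gscore = 0.6, dscore = 0.7,
                         stringsAsFactors = FALSE)
  expect_false(any(rank_and_select(boundary)$rows$is_btc))
})

test_that("melanoma run: RAF/MEK inhibitors are BTCs in clinical skin mode", {
  kb <- curated_kb()
  res <- run_query(melanoma_profile(), kb)
  btc_drugs <- unique(res$btc$drug_name)
  expect_true(all(c("VEMURAFENIB", "TRAMETINIB") %in% btc_drugs))
  expect_false(any(c("EVEROLIMUS", "SIROLIMUS") %in% res$table$drug_name))
  # expanding the search to all cancer types surfaces the MTOR inhibitors
  res_all <- run_query(melanoma_profile(cancer_type = "ALL"), kb)
  expect_true(all(c("EVEROLIMUS", "SIROLIMUS") %in% res_all$table$drug_name))
  # the MAP2K1 genetic dependency contributes a trametinib row
  expect_true(any(res$table$evidence_class == "GENETIC_DEPENDENCY" &
                    res$table$drug_name == "TRAMETINIB"))
})

test_that("clinical results are a subset of discovery results", {
  kb <- curated_kb()
  for (seed in 1:5) {
    rkb <- generate_fixture_kb(seed = seed, n_genes = 30, n_drugs = 15)
    prof <- generate_fixture_profile(rkb, seed = seed + 100, n_altered = 6)
    clin <- run_query(prof, rkb, options = list(mode = "CLINICAL"))
    disc <- run_query(prof, rkb, options = list(mode = "DISCOVERY"))
    key <- function(t) paste(t$drug_id, t$gene, t$evidence_class, t$response)
    expect_true(all(key(clin$table) %in% key(disc$table)))
  }
})

test_that("ranked output is invariant to input record permutation", {
  kb <- curated_kb()
  somatic <- parse_vcf(patient_file("melanoma.somatic.vcf"), "SOMATIC")
  expr <- parse_rnk(patient_file("melanoma.rnk"))
  cnv <- parse_cnv_tsv(patient_file("melanoma.cnv.tsv"))
  base <- run_query(build_profile(somatic = somatic, cnv = cnv, expr = expr,
                                  cancer_type = "SKIN"), kb)
  set.seed(9)
  shuf <- run_query(build_profile(somatic = somatic[sample(nrow(somatic)), ],
                                  cnv = cnv,
                                  expr = expr[sample(nrow(expr)), ],
                                  cancer_type = "SKIN"), kb)
  expect_equal(shuf$table, base$table)
})

test_that("adding kb edges never shrinks the result set", {
  kb <- curated_kb()
  prof <- melanoma_profile(mode = "DISCOVERY")
  base <- run_query(prof, kb)
  kb2 <- kb
  kb2$pathway_edges <- rbind(kb$pathway_edges,
                             data.frame(upstream_gene = "G6PD",
                                        downstream_gene = "MTOR",
                                        stringsAsFactors = FALSE))
  more <- run_query(prof, kb2)
  key <- function(t) paste(t$drug_id, t$gene, t$evidence_class, t$response)
  expect_true(all(key(base$table) %in% key(more$table)))
  expect_gte(nrow(more$table), nrow(base$table))
})
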