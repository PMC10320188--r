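test_that("druggability ladder: best available evidence class wins", {
  kb <- curated_kb()
  expect_equal(druggability_component("BRAF", kb), 1.0)
  expect_equal(druggability_component("NOT_A_GENE", kb), 0.0)

  # gene whose only evidence is a druggable downstream neighbor
  ann <- data.frame(gene = c("UP", "TGT"), driver_role = "NONE",
                    essentiality = 0.5, clinical_level = "NONE",
                    clinical_cancer_types = "", stringsAsFactors = FALSE)
  drugs <- data.frame(drug_id = "D1", name = "DRUG ONE", family = "x",
                      clinical_status = "APPROVED", indications = "SKIN",
                      therapy_type = "TARGETED", stringsAsFactors = FALSE)
  assoc <- data.frame(drug_id = "D1", gene = "TGT",
                      association_type = "DIRECT_TARGET",
                      response = "SENSITIVITY", n_sources = 1L,
                      required_alteration = "ANY", stringsAsFactors = FALSE)
  edges <- data.frame(upstream_gene = "UP", downstream_gene = "TGT",
                      stringsAsFactors = FALSE)
  kb2 <- knowledge_base(drugs = drugs, associations = assoc,
                        gene_annotations = ann, pathway_edges = edges)
  expect_equal(druggability_component("UP", kb2), 0.25)
  # a dependency listing beats pathway membership
  kb3 <- kb2
  kb3$dependencies <- data.frame(context_gene = "TGT",
                                 context_alteration = "ANY",
                                 dependent_gene = "UP",
                                 stringsAsFactors = FALSE)
  expect_equal(druggability_component("UP", kb3), 0.5)
})

test_that("clinical ladder applies the off-tumor penalty", {
  ann <- function(level, types) {
    data.frame(gene = "G", driver_role = "NONE", essentiality = 0,
               clinical_level = level, clinical_cancer_types = types,
               stringsAsFactors = FALSE)
  }
  expect_equal(clinical_component(ann("APPROVED_BIOMARKER", "SKIN"), "SKIN"), 1.0)
  expect_equal(clinical_component(ann("NONE", ""), "SKIN"), 0.0)
  expect_equal(clinical_component(ann("LATE_TRIALS", "BREAST"), "SKIN"),
               0.75 * 0.75)
  expect_equal(clinical_component(ann("LATE_TRIALS", "PAN_CANCER"), "SKIN"),
               0.75)
  expect_equal(clinical_component(ann("EARLY_TRIALS", "BREAST"), "ALL"), 0.5)
  expect_equal(clinical_component(NULL, "SKIN"), 0.0)
})

test_that("concordance bonus rewards agreeing multi-omics channels", {
  expect_equal(concordance_bonus(make_entry(consequences = "missense"),
                                 "ONCOGENE"), 0.0)
  expect_equal(concordance_bonus(make_entry(consequences = "missense",
                                            expr_class = "OVER"), "NONE"),
               0.1)
  expect_equal(concordance_bonus(make_entry(consequences = "missense",
                                            cnv = "AMP",
                                            expr_class = "OVER"),
                                 "ONCOGENE"), 0.2)
  # conflicting directions or anti-driver direction kill the bonus
  expect_equal(concordance_bonus(make_entry(cnv = "AMP",
                                            expr_class = "UNDER"), "NONE"),
               0.0)
  expect_equal(concordance_bonus(make_entry(consequences = "missense",
                                            cnv = "DEL"), "ONCOGENE"), 0.0)
  expect_equal(concordance_bonus(make_entry(consequences = "missense",
                                            cnv = "DEL",
                                            expr_class = "UNDER"), "TSG"),
               0.2)
})

test_that("gscore is the capped weighted sum of its components", {
  expect_equal(compute_gscore(1, 1, 1, 1, 1, 0)$gscore, 1.0)
  expect_equal(compute_gscore(0, 0, 0, 0, 0, 0)$gscore, 0.0)
  # hand-computed: 0.25 + 0.10 + 0.12 + 0.25 + 0.25 + 0.1 = 1.07, capped
  expect_equal(compute_gscore(1, 1, 0.8, 1, 1, 0.1)$gscore, 1.0)
  b <- compute_gscore(0.8, 1, 0.9, 0.75, 0.5625, 0.1)
  expect_equal(b$gscore,
               0.25 * 0.8 + 0.1 * 1 + 0.15 * 0.9 + 0.25 * 0.75 +
                 0.25 * 0.5625 + 0.1)
  expect_error(compute_gscore(1.2, 0, 0, 0, 0),
               class = "drugrank_argument_error")
  cfg <- default_config()
  cfg$gscore$weights["consequence"] <- 0.5
  expect_error(compute_gscore(1, 1, 1, 1, 1, config = cfg),
               class = "drugrank_config_error")
})

test_that("gscore stays in [0,1] and matches a brute-force oracle", {
  cfg <- default_config()
  w <- cfg$gscore$weights
  set.seed(101)
  for (i in 1:2000) {
    comp <- stats::runif(5)
    bonus <- sample(c(0, 0.1, 0.2), 1)
    got <- compute_gscore(comp[1], comp[2], comp[3], comp[4], comp[5],
                          bonus, cfg)$gscore
    oracle <- min(1, w[["consequence"]] * comp[1] + w[["frequency"]] * comp[2] +
                    w[["essentiality"]] * comp[3] +
                    w[["druggability"]] * comp[4] +
                    w[["clinical"]] * comp[5] + bonus)
    expect_true(got >= 0 && got <= 1)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("increasing any single component never decreases the gscore", {
  set.seed(7)
  for (i in 1:200) {
    comp <- stats::runif(5)
    base <- compute_gscore(comp[1], comp[2], comp[3], comp[4], comp[5],
                           0)$gscore
    j <- sample(1:5, 1)
    comp2 <- comp
    comp2[j] <- min(1, comp2[j] + stats::runif(1, 0, 1 - comp2[j]))
    up <- compute_gscore(comp2[1], comp2[2], comp2[3], comp2[4], comp2[5],
                         0)$gscore
    expect_gte(up, base - 1e-12)
  }
})
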