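test_that("status, indication, association and support ladders", {
  kb <- curated_kb()
  vemu <- kb$drugs[kb$drugs$drug_id == "D_VEMU", ]
  ever <- kb$drugs[kb$drugs$drug_id == "D_EVER", ]
  expect_equal(status_component(vemu), 1.0)
  expect_equal(status_component(data.frame(clinical_status = "EXPERIMENTAL")),
               0.2)

  expect_equal(indication_component(vemu, "SKIN"), 1.0)
  expect_equal(indication_component(ever, "SKIN"), 0.5)   # repurposing
  expect_equal(indication_component(ever, "ALL"), 1.0)
  non_cancer <- data.frame(indications = "", stringsAsFactors = FALSE)
  expect_equal(indication_component(non_cancer, "SKIN"), 0.25)
  pan <- data.frame(indications = "PAN_CANCER", stringsAsFactors = FALSE)
  expect_equal(indication_component(pan, "SKIN"), 1.0)

  expect_equal(association_component("DIRECT_TARGET"), 1.0)
  expect_equal(association_component("BIOMARKER"), 0.9)
  expect_equal(association_component("GENETIC_DEPENDENCY"), 0.7)
  expect_equal(association_component("PATHWAY_MEMBER"), 0.5)
  expect_error(association_component("HEARSAY"),
               class = "drugrank_argument_error")

  expect_equal(support_component(1), 0.2)
  expect_equal(support_component(5), 1.0)
  expect_equal(support_component(10), 1.0)
  expect_error(support_component(0), class = "drugrank_argument_error")
})

test_that("collective impact is a noisy-OR over linked gene GScores", {
  expect_equal(collective_impact(1.0), 0.5)
  expect_equal(collective_impact(c(1.0, 1.0)), 0.75)
  expect_equal(collective_impact(0), 0.0)
  expect_error(collective_impact(numeric(0)),
               class = "drugrank_argument_error")
  # strictly increases with each additional positively scored gene
  set.seed(11)
  for (i in 1:100) {
    g <- stats::runif(sample(1:5, 1))
    extra <- stats::runif(1, 0.05, 1)
    expect_gt(collective_impact(c(g, extra)), collective_impact(g))
    expect_lt(collective_impact(g), 1)
  }
})

test_that("dscore is the signed weighted sum of its components", {
  expect_equal(compute_dscore(1, 1, 1, 1, 1, "SENSITIVITY")$dscore, 1.0)
  expect_equal(compute_dscore(1, 1, 1, 1, 1, "RESISTANCE")$dscore, -1.0)
  # hand-computed: .35 + .2 + .18 + .02 + .075 = 0.825
  expect_equal(compute_dscore(1, 1, 0.9, 0.2, 0.5, "SENSITIVITY")$dscore,
               0.825)
  cfg <- default_config()
  cfg$dscore$weights["status"] <- 0.9
  expect_error(compute_dscore(1, 1, 1, 1, 1, config = cfg),
               class = "drugrank_config_error")
})

test_that("dscore range, sign law and oracle equivalence on random draws", {
  cfg <- default_config()
  w <- cfg$dscore$weights
  set.seed(202)
  for (i in 1:2000) {
    comp <- stats::runif(5)
    resp <- sample(c("SENSITIVITY", "RESISTANCE"), 1)
    d <- compute_dscore(comp[1], comp[2], comp[3], comp[4], comp[5], resp,
                        cfg)$dscore
    oracle <- sum(w[c("status", "indication", "association", "support",
                      "collective")] * comp) *
      (if (resp == "SENSITIVITY") 1 else -1)
    expect_true(abs(d) <= 1)
    expect_equal(d, oracle, tolerance = 1e-12)
    if (abs(d) > 0) {
      expect_identical(d < 0, resp == "RESISTANCE")
    }
  }
})

test_that("dscore magnitude is monotone in support and status upgrades", {
  set.seed(33)
  for (i in 1:100) {
    comp <- stats::runif(3)  # indication, association, collective
    n <- sample(1:9, 1)
    lo <- compute_dscore(1, comp[1], comp[2], support_component(n),
                         comp[3], "SENSITIVITY")$dscore
    hi <- compute_dscore(1, comp[1], comp[2], support_component(n + 1),
                         comp[3], "SENSITIVITY")$dscore
    expect_gte(abs(hi), abs(lo) - 1e-12)
    ladder <- default_config()$dscore$status_ladder
    mags <- vapply(c("EXPERIMENTAL", "CLINICAL_TRIAL", "APPROVED"),
                   function(s) abs(compute_dscore(ladder[[s]], comp[1],
                                                  comp[2], 0.4, comp[3],
                                                  "RESISTANCE")$dscore),
                   numeric(1))
    expect_true(all(diff(mags) >= -1e-12))
  }
})
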