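# Seeded random draws used by the property tests and the acceptance
# script: random score contexts for the two engines, and random end-to-end
# prioritization runs.

#' Random GScore draws
#'
#' Generates `n` random gene contexts (independent uniform component
#' vectors plus a random concordance bonus from the configured schedule)
#' and scores each with [compute_gscore()].
#'
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param config Configuration list.
#' @return Numeric vector of `n` GScores.
#' @export
sample_gscores <- function(n, seed = 1L, config = default_config()) {
  withr::with_seed(seed, {
    bonus_values <- c(0, unname(config$gscore$concordance_bonus))
    vapply(seq_len(n), function(i) {
      compute_gscore(stats::runif(1), stats::runif(1), stats::runif(1),
                     stats::runif(1), stats::runif(1),
                     sample(bonus_values, 1), config)$gscore
    }, numeric(1))
  })
}

#' Random DScore draws
#'
#' Generates `n` random drug-gene association contexts: random clinical
#' status, indication scenario, evidence class, source count, collective
#' gene set (1-4 genes with uniform GScores) and response direction; scores
#' each with [compute_dscore()].
#'
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param config Configuration list.
#' @return Data frame with columns `dscore`, `response`.
#' @export
sample_dscores <- function(n, seed = 2L, config = default_config()) {
  withr::with_seed(seed, {
    status_v <- unname(config$dscore$status_ladder)
    indic_v <- unname(config$dscore$indication_ladder)
    assoc_v <- unname(config$dscore$association_ladder)
    response <- sample(RESPONSES, n, replace = TRUE)
    dscore <- vapply(seq_len(n), function(i) {
      compute_dscore(
        status = sample(status_v, 1),
        indication = sample(indic_v, 1),
        association = sample(assoc_v, 1),
        support = support_component(sample(1:10, 1), config),
        collective = collective_impact(stats::runif(sample(1:4, 1))),
        response = response[i], config = config
      )$dscore
    }, numeric(1))
    data.frame(dscore = dscore, response = response,
               stringsAsFactors = FALSE)
  })
}

#' Generate a random patient profile over a knowledge base
#'
#' Samples `n_altered` genes from the knowledge base and gives each a
#' random combination of alteration channels (somatic variant with random
#' consequence / VAF / population frequency, copy-number status, extreme
#' expression), embedded in a full expression ranking over every knowledge
#' base gene. Deterministic for a fixed seed.
#'
#' @param kb A [knowledge_base()].
#' @param seed Integer seed.
#' @param n_altered Number of altered genes to sample.
#' @param cancer_type Queried cancer type; random organ code when `NULL`.
#' @param mode Query mode for the profile.
#' @return A `patient_profile`.
#' @export
generate_fixture_profile <- function(kb, seed = 1L, n_altered = 8L,
                                     cancer_type = NULL,
                                     mode = "DISCOVERY") {
  genes <- kb$gene_annotations$gene
  if (length(genes) == 0) {
    dr_abort("knowledge base has no annotated genes",
             "drugrank_argument_error")
  }
  withr::with_seed(seed, {
    cancer_type <- cancer_type %||%
      sample(setdiff(cancer_type_codes(), "PAN_CANCER"), 1)
    picked <- sample(genes, min(n_altered, length(genes)))
    somatic <- NULL
    cnv <- NULL
    expr <- data.frame(gene = genes,
                       rank_value = round(stats::rnorm(length(genes)), 3),
                       stringsAsFactors = FALSE)
    for (g in picked) {
      channels <- sample(c("snv", "cnv", "expr"), sample(1:3, 1))
      if ("snv" %in% channels) {
        rec <- data.frame(
          chrom = as.character(sample(1:22, 1)),
          pos = sample(1e4:1e7, 1),
          ref = sample(c("A", "C", "G", "T"), 1),
          alt = sample(c("A", "C", "G", "T"), 1),
          origin = "SOMATIC",
          genotype = sample(c("HET", "HOM"), 1, prob = c(0.8, 0.2)),
          vaf = round(stats::runif(1, 0.02, 0.9), 3),
          gene = g,
          consequence = sample(CONSEQUENCE_TERMS, 1),
          predicted_deleterious = sample(c(TRUE, FALSE), 1),
          population_af = if (stats::runif(1) < 0.3)
            signif(stats::runif(1, 1e-5, 0.02), 3) else NA_real_,
          stringsAsFactors = FALSE)
        somatic <- rbind(somatic, rec)
      }
      if ("cnv" %in% channels) {
        cnv <- rbind(cnv, data.frame(gene = g,
                                     status = sample(c("AMP", "DEL"), 1),
                                     stringsAsFactors = FALSE))
      }
      if ("expr" %in% channels) {
        expr$rank_value[expr$gene == g] <- round(
          sample(c(-1, 1), 1) * stats::runif(1, 5, 10), 3)
      }
    }
    build_profile(somatic = somatic, cnv = cnv, expr = expr,
                  cancer_type = cancer_type, mode = mode)
  })
}

#' Collect BTC rows across random end-to-end runs
#'
#' For each seed, generates a random knowledge base and patient profile,
#' runs [run_query()] in discovery mode, and collects every row flagged as
#' a Best Therapeutic Candidate.
#'
#' @param seeds Integer vector of run seeds.
#' @param n_genes,n_drugs Knowledge-base size per run.
#' @param n_altered Altered genes per profile.
#' @param config Configuration list.
#' @return Data frame of BTC rows pooled across runs (may have zero rows).
#' @export
random_btc_rows <- function(seeds, n_genes = 40L, n_drugs = 25L,
                            n_altered = 8L, config = default_config()) {
  out <- lapply(seeds, function(s) {
    kb <- generate_fixture_kb(seed = s, n_genes = n_genes,
                              n_drugs = n_drugs, curated = FALSE)
    prof <- generate_fixture_profile(kb, seed = s + 500L,
                                     n_altered = n_altered)
    res <- run_query(prof, kb, config = config)
    res$btc
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0) {
    return(data.frame(gscore = numeric(0), dscore = numeric(0)))
  }
  do.call(rbind, out)
}
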