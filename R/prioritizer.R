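# Evidence classification, dependency / pathway expansion, query modes,
# ranking and Best-Therapeutic-Candidate selection.

evidence_row <- function(drug_id, gene, evidence_class, response, n_sources,
                         gscore) {
  data.frame(drug_id = drug_id, gene = gene, evidence_class = evidence_class,
             response = response, n_sources = n_sources, gscore = gscore,
             stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  evidence_row(character(0), character(0), character(0), character(0),
               integer(0), numeric(0))
}

#' Classify the druggability evidence of an altered gene
#'
#' Returns the direct-target and biomarker associations whose required
#' alteration pattern matches the gene's observed alterations. Genetic
#' dependencies and pathway members are contributed by
#' [expand_dependencies()] and [expand_pathway()].
#'
#' @param gene Gene symbol present in the profile.
#' @param profile A `patient_profile`.
#' @param kb A [knowledge_base()].
#' @param config Configuration list.
#' @return Data frame with columns `evidence_class, drug_id, response,
#'   n_sources` (zero rows for an unaltered or unmatched gene).
#' @export
classify_evidence <- function(gene, profile, kb, config = default_config()) {
  entry <- profile$genes[[gene]]
  out <- data.frame(evidence_class = character(0), drug_id = character(0),
                    response = character(0), n_sources = integer(0),
                    stringsAsFactors = FALSE)
  if (is.null(entry) || !is_altered_entry(entry)) return(out)
  ann <- kb$gene_annotations[kb$gene_annotations$gene == gene, , drop = FALSE]
  tokens <- alteration_tokens(entry, ann, config)
  a <- kb$associations[kb$associations$gene == gene, , drop = FALSE]
  if (nrow(a) == 0) return(out)
  hit <- vapply(a$required_alteration, matches_required, logical(1),
                tokens = tokens)
  a <- a[hit, , drop = FALSE]
  data.frame(evidence_class = a$association_type, drug_id = a$drug_id,
             response = a$response, n_sources = a$n_sources,
             stringsAsFactors = FALSE)
}

direct_biomarker_rows <- function(profile, kb, gene_scores, config) {
  rows <- lapply(gene_scores$gene, function(g) {
    ev <- classify_evidence(g, profile, kb, config)
    if (nrow(ev) == 0) return(NULL)
    evidence_row(ev$drug_id, g, ev$evidence_class, ev$response, ev$n_sources,
                 gene_scores$gscore[gene_scores$gene == g])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) empty_evidence() else rows
}

#' Expand genetic dependencies into derived targets
#'
#' For every dependency pair whose context gene and alteration pattern
#' match the profile, the dependent gene is emitted as a
#' `GENETIC_DEPENDENCY` target; its drugs are the dependent gene's
#' direct-target drugs and the derived rows inherit the context gene's
#' GScore times the dependency decay (0.9 by default). Multiple matching
#' pairs to the same dependent gene are merged, keeping the best inherited
#' GScore.
#'
#' @param profile A `patient_profile`.
#' @param kb A [knowledge_base()].
#' @param gene_scores Data frame with columns `gene`, `gscore` for the
#'   altered genes.
#' @param config Configuration list.
#' @return Evidence-row data frame (possibly empty).
#' @export
expand_dependencies <- function(profile, kb, gene_scores,
                                config = default_config()) {
  dep <- kb$dependencies
  if (nrow(dep) == 0 || nrow(gene_scores) == 0) return(empty_evidence())
  out <- list()
  for (i in seq_len(nrow(dep))) {
    ctx <- dep$context_gene[i]
    if (!(ctx %in% gene_scores$gene)) next
    entry <- profile$genes[[ctx]]
    ann <- kb$gene_annotations[kb$gene_annotations$gene == ctx, , drop = FALSE]
    tokens <- alteration_tokens(entry, ann, config)
    if (!matches_required(tokens, dep$context_alteration[i])) next
    g_inherit <- gene_scores$gscore[gene_scores$gene == ctx] *
      config$prioritizer$dependency_decay
    target <- dep$dependent_gene[i]
    a <- kb$associations[kb$associations$gene == target &
                           kb$associations$association_type == "DIRECT_TARGET",
                         , drop = FALSE]
    if (nrow(a) == 0) next
    out[[length(out) + 1L]] <- evidence_row(a$drug_id, target,
                                            "GENETIC_DEPENDENCY", a$response,
                                            a$n_sources, g_inherit)
  }
  rows <- do.call(rbind, out)
  if (is.null(rows)) return(empty_evidence())
  # de-duplicate (drug, gene, response), keeping the best inherited score
  rows <- rows[order(rows$drug_id, rows$gene, rows$response, -rows$gscore), ]
  rows <- rows[!duplicated(rows[, c("drug_id", "gene", "response")]), ]
  rownames(rows) <- NULL
  rows
}

#' Expand druggable downstream pathway members
#'
#' Breadth-first walk along directed pathway edges from every altered gene
#' (cycles terminated by a visited set). Any reached gene with a
#' direct-target drug is emitted as a `PATHWAY_MEMBER` with the origin
#' gene's GScore decayed per hop (0.75 per edge by default); multiple
#' origins keep the best decayed score.
#'
#' @inheritParams expand_dependencies
#' @param max_depth Maximum number of hops (default from `config`).
#' @return Evidence-row data frame (possibly empty).
#' @export
expand_pathway <- function(profile, kb, gene_scores,
                           max_depth = NULL, config = default_config()) {
  max_depth <- max_depth %||% config$prioritizer$max_depth
  if (max_depth < 1) dr_abort("max_depth must be >= 1",
                              "drugrank_argument_error")
  if (nrow(kb$pathway_edges) == 0 || nrow(gene_scores) == 0) {
    return(empty_evidence())
  }
  decay <- config$prioritizer$pathway_decay
  out <- list()
  for (i in seq_len(nrow(gene_scores))) {
    origin <- gene_scores$gene[i]
    reach <- bfs_downstream(kb$pathway_edges, origin, max_depth)
    for (target in names(reach)) {
      a <- kb$associations[kb$associations$gene == target &
                             kb$associations$association_type == "DIRECT_TARGET",
                           , drop = FALSE]
      if (nrow(a) == 0) next
      g <- gene_scores$gscore[i] * decay^reach[[target]]
      out[[length(out) + 1L]] <- evidence_row(a$drug_id, target,
                                              "PATHWAY_MEMBER", a$response,
                                              a$n_sources, g)
    }
  }
  rows <- do.call(rbind, out)
  if (is.null(rows)) return(empty_evidence())
  rows <- rows[order(rows$drug_id, rows$gene, rows$response, -rows$gscore), ]
  rows <- rows[!duplicated(rows[, c("drug_id", "gene", "response")]), ]
  rownames(rows) <- NULL
  rows
}

#' Filter scored rows by query mode
#'
#' Clinical mode keeps drugs that are approved or in clinical trials, with
#' direct-target / biomarker / genetic-dependency evidence, and indicated
#' for the queried cancer type (repurposing and non-cancer drugs are
#' discovery-only; querying `"ALL"` accepts any cancer indication).
#' Discovery mode keeps everything, so the clinical result is always a
#' subset of the discovery result on identical input.
#'
#' @param rows Scored results table.
#' @param options List with `mode` (`"CLINICAL"`/`"DISCOVERY"`).
#' @return Filtered rows.
#' @export
apply_mode <- function(rows, options) {
  mode <- options$mode %||% "CLINICAL"
  if (mode == "DISCOVERY" || nrow(rows) == 0) return(rows)
  keep <- rows$clinical_status %in% c("APPROVED", "CLINICAL_TRIAL") &
    rows$evidence_class %in% c("DIRECT_TARGET", "BIOMARKER",
                               "GENETIC_DEPENDENCY") &
    rows$indication_component >= 1
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank rows and select the Best Therapeutic Candidates
#'
#' Stable sort by DScore (descending), then per-row GScore (descending),
#' then normalized drug name (ascending, for reproducible output). A row is
#' flagged BTC iff its evidence gene's GScore exceeds 0.6 and its DScore
#' exceeds 0.7 (both strict).
#'
#' @param rows Scored results table.
#' @param config Configuration list (thresholds under `prioritizer`).
#' @return List with `rows` (ranked, with `rank` and `is_btc` columns) and
#'   `btc` (the BTC subset in ranking order).
#' @export
rank_and_select <- function(rows, config = default_config()) {
  if (nrow(rows)) {
    ord <- order(-rows$dscore, -rows$gscore, normalize_drug_name(rows$drug_name),
                 rows$gene, method = "radix")
    rows <- rows[ord, , drop = FALSE]
    rows$rank <- seq_len(nrow(rows))
    rows$is_btc <- rows$gscore > config$prioritizer$btc_gscore &
      rows$dscore > config$prioritizer$btc_dscore
  } else {
    rows$rank <- integer(0)
    rows$is_btc <- logical(0)
  }
  rownames(rows) <- NULL
  list(rows = rows, btc = rows[rows$is_btc, , drop = FALSE])
}

#' Run a full prioritization query
#'
#' End-to-end pipeline: scores every altered gene (GScore), classifies
#' druggability evidence, expands genetic dependencies and pathway members,
#' scores every drug-gene association (DScore, including the collective
#' gene impact over all queried druggable genes linked to each drug),
#' matches germline variants against the pharmacogenetic rules, applies the
#' query mode, ranks, selects the Best Therapeutic Candidates and builds
#' the run summary. Deterministic for identical inputs.
#'
#' @param profile A `patient_profile` from [build_profile()].
#' @param kb A [knowledge_base()].
#' @param options Optional list overriding `mode` and/or `cancer_type`.
#' @param config Configuration list.
#' @return A `drug_ranking` object: list with `table` (ranked results),
#'   `btc`, `gene_scores`, `pgx` (pharmacogenetic recommendations),
#'   `summary`, `mode`, `cancer_type`, `kb_version`.
#' @export
run_query <- function(profile, kb, options = NULL,
                      config = default_config()) {
  if (!inherits(profile, "patient_profile")) {
    dr_abort("profile must be a patient_profile", "drugrank_argument_error")
  }
  mode <- options$mode %||% profile$mode
  cancer_type <- options$cancer_type %||% profile$cancer_type
  if (!(cancer_type %in% c(cancer_type_codes(), "ALL"))) {
    dr_abort(sprintf("unknown cancer type '%s'", cancer_type),
             "drugrank_argument_error")
  }

  genes <- altered_genes(profile)
  breakdowns <- lapply(genes, gene_gscore, profile = profile, kb = kb,
                       cancer_type = cancer_type, config = config)
  gene_scores <- if (length(genes)) {
    data.frame(gene = genes,
               do.call(rbind, lapply(breakdowns, function(b)
                 as.data.frame(unclass(b)))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), gscore = numeric(0),
               stringsAsFactors = FALSE)
  }

  rows <- rbind(direct_biomarker_rows(profile, kb, gene_scores, config),
                expand_dependencies(profile, kb, gene_scores, config),
                expand_pathway(profile, kb, gene_scores, config = config))

  if (nrow(rows)) {
    di <- match(rows$drug_id, kb$drugs$drug_id)
    rows$drug_name <- kb$drugs$name[di]
    rows$family <- kb$drugs$family[di]
    rows$clinical_status <- kb$drugs$clinical_status[di]
    rows$therapy_type <- kb$drugs$therapy_type[di]

    # per-drug collective impact over each linked gene's best GScore
    collective <- vapply(unique(rows$drug_id), function(d) {
      sub <- rows[rows$drug_id == d, ]
      collective_impact(vapply(unique(sub$gene), function(g)
        max(sub$gscore[sub$gene == g]), numeric(1)))
    }, numeric(1))

    comp <- lapply(seq_len(nrow(rows)), function(i) {
      drug <- kb$drugs[di[i], , drop = FALSE]
      compute_dscore(
        status = status_component(drug, config),
        indication = indication_component(drug, cancer_type, config),
        association = association_component(rows$evidence_class[i], config),
        support = support_component(rows$n_sources[i], config),
        collective = collective[[rows$drug_id[i]]],
        response = rows$response[i], config = config
      )
    })
    rows$status_component <- vapply(comp, `[[`, numeric(1), "status_component")
    rows$indication_component <- vapply(comp, `[[`, numeric(1),
                                        "indication_component")
    rows$association_component <- vapply(comp, `[[`, numeric(1),
                                         "association_component")
    rows$support_component <- vapply(comp, `[[`, numeric(1),
                                     "support_component")
    rows$collective_impact <- vapply(comp, `[[`, numeric(1),
                                     "collective_impact")
    rows$dscore <- vapply(comp, `[[`, numeric(1), "dscore")

    # alteration icons for the evidence gene
    flag <- function(g, f) {
      e <- profile$genes[[g]]
      if (is.null(e)) return(f(empty_profile_entry(g)))
      f(e)
    }
    rows$has_snv <- vapply(rows$gene, flag, logical(1),
                           f = function(e) nrow(e$somatic) > 0)
    rows$has_germline <- vapply(rows$gene, flag, logical(1),
                                f = function(e) nrow(e$germline) > 0)
    rows$cnv_status <- vapply(rows$gene, flag, character(1),
                              f = function(e) e$cnv)
    rows$expr_class <- vapply(rows$gene, flag, character(1),
                              f = function(e) e$expr_class)
  } else {
    for (col in c("drug_name", "family", "clinical_status", "therapy_type",
                  "cnv_status", "expr_class")) rows[[col]] <- character(0)
    for (col in c("status_component", "indication_component",
                  "association_component", "support_component",
                  "collective_impact", "dscore")) rows[[col]] <- numeric(0)
    for (col in c("has_snv", "has_germline")) rows[[col]] <- logical(0)
  }

  germline_all <- do.call(rbind, c(list(variant_columns()),
                                   lapply(profile$genes, `[[`, "germline")))
  recs <- match_pgx(germline_all, kb$pgx_rules)

  kept <- apply_mode(rows, list(mode = mode))
  ranked <- rank_and_select(kept, config)
  table <- annotate_rows(ranked$rows, recs)
  btc <- table[table$is_btc, , drop = FALSE]

  result <- structure(
    list(table = table, btc = btc, gene_scores = gene_scores, pgx = recs,
         mode = mode, cancer_type = cancer_type, kb_version = kb$version),
    class = "drug_ranking"
  )
  result$summary <- summarize(table, profile,
                              list(mode = mode, cancer_type = cancer_type),
                              kb_version = kb$version, config = config)
  result
}

#' @export
print.drug_ranking <- function(x, ...) {
  cat("<drug_ranking>", nrow(x$table), "row(s),", nrow(x$btc), "BTC(s);",
      "mode =", x$mode, "; cancer_type =", x$cancer_type, "\n")
  if (nrow(x$table)) {
    show <- utils::head(x$table[, c("rank", "drug_name", "gene",
                                    "evidence_class", "response", "gscore",
                                    "dscore", "is_btc")], 10)
    print(show, row.names = FALSE)
  }
  invisible(x)
}
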