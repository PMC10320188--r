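# Per-gene actionability score (GScore) in [0,1]: weighted combination of
# consequence impact, population rarity, cancer essentiality, druggability
# and clinical evidence, plus a multi-omics concordance bonus, capped at 1.

# breadth-first walk along directed pathway edges; returns named integer
# vector of depths for every gene reachable from `start` within max_depth
bfs_downstream <- function(edges, start, max_depth) {
  depths <- integer(0)
  frontier <- start
  visited <- start
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    nxt <- unique(edges$downstream_gene[edges$upstream_gene %in% frontier])
    nxt <- setdiff(nxt, visited)
    if (length(nxt)) depths[nxt] <- d
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  depths
}

direct_target_drugs <- function(kb, gene) {
  a <- kb$associations
  a$drug_id[a$gene == gene & a$association_type == "DIRECT_TARGET"]
}

#' Druggability component of the gene score
#'
#' Best available evidence class wins: direct target 1.0, biomarker 0.75,
#' dependent gene of any genetic-dependency pair 0.5, druggable downstream
#' pathway member within the configured depth 0.25, none 0.0. An unknown
#' gene scores 0.
#'
#' @param gene Gene symbol.
#' @param kb A [knowledge_base()].
#' @param config Configuration list.
#' @return Score in `[0, 1]`.
#' @export
druggability_component <- function(gene, kb, config = default_config()) {
  ladder <- config$gscore$druggability_ladder
  a <- kb$associations[kb$associations$gene == gene, , drop = FALSE]
  if (any(a$association_type == "DIRECT_TARGET")) return(ladder[["DIRECT_TARGET"]])
  if (any(a$association_type == "BIOMARKER")) return(ladder[["BIOMARKER"]])
  if (gene %in% kb$dependencies$dependent_gene) {
    return(ladder[["GENETIC_DEPENDENCY"]])
  }
  reach <- bfs_downstream(kb$pathway_edges, gene,
                          config$prioritizer$max_depth)
  if (length(reach)) {
    druggable <- vapply(names(reach), function(g)
      length(direct_target_drugs(kb, g)) > 0, logical(1))
    if (any(druggable)) return(ladder[["PATHWAY_MEMBER"]])
  }
  ladder[["NONE"]]
}

#' Clinical-implication component of the gene score
#'
#' Ladder over the gene's clinical evidence level (approved biomarker 1.0
#' down to none 0.0), multiplied by an off-tumor penalty when the queried
#' cancer type is not among the gene's clinical cancer types (pan-cancer
#' annotations always match, as does a query for `"ALL"`).
#'
#' @param annotation Single-row slice of `gene_annotations`, or `NULL`.
#' @param cancer_type Queried cancer-type code or `"ALL"`.
#' @param config Configuration list.
#' @return Score in `[0, 1]`.
#' @export
clinical_component <- function(annotation, cancer_type = "ALL",
                               config = default_config()) {
  if (is.null(annotation) || nrow(annotation) == 0) return(0.0)
  base <- config$gscore$clinical_ladder[[annotation$clinical_level[1]]]
  types <- split_multi(annotation$clinical_cancer_types[1])[[1]]
  matched <- cancer_type == "ALL" || cancer_type %in% types ||
    "PAN_CANCER" %in% types
  if (!matched) base <- base * config$gscore$off_tumor_penalty
  base
}

#' Multi-omics concordance bonus
#'
#' Counts the altered channels of a gene (mutation, copy number,
#' expression) and rewards agreement: 0 for a single channel, +0.1 for two
#' concordant channels, +0.2 for three. Concordance requires all
#' alterations to push the same driver direction (activation for an
#' oncogene: AMP / overexpression; loss for a tumor suppressor: DEL /
#' underexpression; small variants are direction-neutral). Conflicting
#' directions score 0.
#'
#' @param entry A per-gene entry from a `patient_profile`.
#' @param driver_role Driver annotation of the gene.
#' @param config Configuration list.
#' @return Bonus in `{0, 0.1, 0.2}` (default schedule).
#' @export
concordance_bonus <- function(entry, driver_role = "NONE",
                              config = default_config()) {
  has_snv <- nrow(entry$somatic) > 0
  has_cnv <- !is.na(entry$cnv)
  has_expr <- entry$expr_class %in% c("OVER", "UNDER")
  n <- sum(has_snv, has_cnv, has_expr)
  if (n < 2) return(0.0)
  up <- (has_cnv && entry$cnv == "AMP") || (has_expr && entry$expr_class == "OVER")
  down <- (has_cnv && entry$cnv == "DEL") ||
    (has_expr && entry$expr_class == "UNDER")
  if (up && down) return(0.0)
  if (identical(driver_role, "ONCOGENE") && down) return(0.0)
  if (identical(driver_role, "TSG") && up) return(0.0)
  sched <- config$gscore$concordance_bonus
  if (n == 2) sched[["two_channels"]] else sched[["three_channels"]]
}

#' Combine gene-score components into a GScore
#'
#' `gscore = min(1, sum(w_i * component_i) + concordance_bonus)` with
#' non-negative weights summing to 1. Components must each lie in `[0, 1]`.
#'
#' @param consequence,frequency,essentiality,druggability,clinical Component
#'   scores in `[0, 1]`.
#' @param bonus Concordance bonus in `[0, 1]`.
#' @param config Configuration list (weights under `gscore$weights`).
#' @return A `gscore_breakdown` list with all components and the combined
#'   `gscore`.
#' @export
compute_gscore <- function(consequence, frequency, essentiality,
                           druggability, clinical, bonus = 0,
                           config = default_config()) {
  w <- check_weights(config$gscore$weights, "gscore")
  comp <- c(consequence = consequence, frequency = frequency,
            essentiality = essentiality, druggability = druggability,
            clinical = clinical)
  if (any(is.na(comp)) || any(comp < 0) || any(comp > 1) ||
      is.na(bonus) || bonus < 0 || bonus > 1) {
    dr_abort("gscore components and bonus must lie in [0,1]",
             "drugrank_argument_error")
  }
  g <- min(1, sum(w[names(comp)] * comp) + bonus)
  structure(
    list(consequence_component = consequence, frequency_component = frequency,
         essentiality_component = essentiality,
         druggability_component = druggability,
         clinical_component = clinical, concordance_bonus = bonus,
         gscore = g),
    class = "gscore_breakdown"
  )
}

#' Score one gene of a patient profile
#'
#' Assembles the gene-score components from the profile entry and the
#' knowledge base (consequence = max over per-alteration impacts; rarity
#' from the highest-impact somatic variant, 1.0 when there is none) and
#' combines them with [compute_gscore()].
#'
#' @param gene Gene symbol present in the profile.
#' @param profile A `patient_profile`.
#' @param kb A [knowledge_base()].
#' @param cancer_type Queried cancer-type code or `"ALL"`; defaults to the
#'   profile's.
#' @param config Configuration list.
#' @return A `gscore_breakdown`.
#' @export
gene_gscore <- function(gene, profile, kb, cancer_type = NULL,
                        config = default_config()) {
  entry <- profile$genes[[gene]]
  if (is.null(entry)) {
    dr_abort(sprintf("gene '%s' is not present in the profile", gene),
             "drugrank_argument_error")
  }
  cancer_type <- cancer_type %||% profile$cancer_type
  ann <- kb$gene_annotations[kb$gene_annotations$gene == gene, , drop = FALSE]
  role <- if (nrow(ann)) ann$driver_role[1] else "NONE"

  impacts <- alteration_inputs(entry, ann, config)
  consequence <- if (length(impacts)) min(1, max(impacts)) else 0.0

  frequency <- 1.0
  if (nrow(entry$somatic)) {
    var_imp <- impacts[startsWith(names(impacts), "SNV:")]
    if (length(var_imp)) {
      best <- which(var_imp == max(var_imp))
      frequency <- max(vapply(best, function(i)
        frequency_term(entry$somatic$population_af[i], config), numeric(1)))
    }
  }

  compute_gscore(
    consequence = consequence,
    frequency = frequency,
    essentiality = if (nrow(ann)) ann$essentiality[1] else 0.0,
    druggability = druggability_component(gene, kb, config),
    clinical = clinical_component(ann, cancer_type, config),
    bonus = concordance_bonus(entry, role, config),
    config = config
  )
}
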