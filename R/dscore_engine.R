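# Per-drug suitability score (DScore) in [-1,1]: signed weighted
# combination of clinical status, indication match, association class,
# curation support and collective gene impact; the sign encodes the
# response direction (sensitivity positive, resistance negative).

#' Clinical-status component of the drug score
#'
#' @param drug Single-row slice of the `drugs` table.
#' @param config Configuration list.
#' @return Score in `[0, 1]` (approved 1.0, clinical trial 0.6,
#'   experimental 0.2 by default).
#' @export
status_component <- function(drug, config = default_config()) {
  config$dscore$status_ladder[[drug$clinical_status[1]]]
}

#' Indication component of the drug score
#'
#' 1.0 when the drug is indicated for the queried cancer type (pan-cancer
#' indications always match; a query for `"ALL"` treats any cancer
#' indication as a match), 0.5 when indicated for a different cancer
#' (repurposing), 0.25 for non-cancer drugs.
#'
#' @param drug Single-row slice of the `drugs` table.
#' @param cancer_type Queried cancer-type code or `"ALL"`.
#' @param config Configuration list.
#' @return Score in `[0, 1]`.
#' @export
indication_component <- function(drug, cancer_type = "ALL",
                                 config = default_config()) {
  ladder <- config$dscore$indication_ladder
  inds <- split_multi(drug$indications[1])[[1]]
  if (length(inds) == 0) return(ladder[["non_cancer"]])
  if (cancer_type == "ALL" || cancer_type %in% inds || "PAN_CANCER" %in% inds) {
    return(ladder[["match"]])
  }
  ladder[["other_cancer"]]
}

#' Association-class component of the drug score
#'
#' Ladder over the four druggability evidence classes: direct target 1.0,
#' biomarker 0.9, genetic dependency 0.7, pathway member 0.5.
#'
#' @param evidence_class One of `DIRECT_TARGET`, `BIOMARKER`,
#'   `GENETIC_DEPENDENCY`, `PATHWAY_MEMBER`.
#' @param config Configuration list.
#' @return Score in `[0, 1]`.
#' @export
association_component <- function(evidence_class,
                                  config = default_config()) {
  if (!(evidence_class %in% EVIDENCE_CLASSES)) {
    dr_abort(sprintf("unknown evidence class '%s'", evidence_class),
             "drugrank_argument_error")
  }
  config$dscore$association_ladder[[evidence_class]]
}

#' Curation-support component of the drug score
#'
#' `min(1, n_sources / saturation)` with saturation at 5 sources by
#' default; monotone non-decreasing.
#'
#' @param n_sources Number of curated databases supporting the association
#'   (>= 1).
#' @param config Configuration list.
#' @return Score in `(0, 1]`.
#' @export
support_component <- function(n_sources, config = default_config()) {
  if (is.na(n_sources) || n_sources < 1) {
    dr_abort("n_sources must be >= 1", "drugrank_argument_error")
  }
  min(1, n_sources / config$dscore$support_saturation)
}

#' Collective gene impact of a drug
#'
#' Noisy-OR over the GScores of the queried druggable genes linked to the
#' drug: `1 - prod(1 - g_i / 2)`. Strictly increases with every additional
#' gene of positive GScore and stays in `[0, 1)`, realizing the rule that
#' drugs targeting more druggable genes are prioritized, with diminishing
#' returns.
#'
#' @param gscores Numeric vector of per-gene GScores (non-empty, each in
#'   `[0, 1]`).
#' @return Score in `[0, 1)`.
#' @export
collective_impact <- function(gscores) {
  if (length(gscores) == 0) {
    dr_abort("collective_impact requires at least one gene",
             "drugrank_argument_error")
  }
  if (any(is.na(gscores)) || any(gscores < 0) || any(gscores > 1)) {
    dr_abort("gscores must lie in [0,1]", "drugrank_argument_error")
  }
  1 - prod(1 - gscores / 2)
}

#' Combine drug-score components into a DScore
#'
#' `magnitude = sum(w_i * component_i)` in `[0, 1]`;
#' `dscore = +magnitude` for sensitivity associations and `-magnitude` for
#' resistance.
#'
#' @param status,indication,association,support,collective Component scores
#'   in `[0, 1]`.
#' @param response `"SENSITIVITY"` or `"RESISTANCE"`.
#' @param config Configuration list (weights under `dscore$weights`).
#' @return A `dscore_breakdown` list with all components, the response
#'   sign, and the signed `dscore`.
#' @export
compute_dscore <- function(status, indication, association, support,
                           collective, response = c("SENSITIVITY",
                                                    "RESISTANCE"),
                           config = default_config()) {
  response <- match.arg(response)
  w <- check_weights(config$dscore$weights, "dscore")
  comp <- c(status = status, indication = indication,
            association = association, support = support,
            collective = collective)
  if (any(is.na(comp)) || any(comp < 0) || any(comp > 1)) {
    dr_abort("dscore components must lie in [0,1]", "drugrank_argument_error")
  }
  magnitude <- sum(w[names(comp)] * comp)
  sign <- if (response == "SENSITIVITY") 1 else -1
  structure(
    list(status_component = status, indication_component = indication,
         association_component = association, support_component = support,
         collective_impact = collective, response_sign = sign,
         dscore = sign * magnitude),
    class = "dscore_breakdown"
  )
}
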