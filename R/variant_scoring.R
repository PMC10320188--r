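# Converts alterations into per-alteration impact scores on a common [0,1]
# scale: consequence impact for small variants, fixed mappings for CNV,
# expression and assumed (gene-list) alterations, plus the population
# allele-frequency rarity term.

#' Impact score of a variant consequence
#'
#' Fixed table: frameshift / stop_gained / splice = 1.0; missense 0.8 with a
#' deleteriousness prediction, 0.5 without; inframe_indel 0.6;
#' synonymous / other 0.0. Truncating terms in a pure oncogene are
#' down-weighted by 0.5 (loss of function in an oncogene is rarely
#' activating). All constants are configurable.
#'
#' @param term Controlled consequence term (one of
#'   `r paste(CONSEQUENCE_TERMS, collapse = ", ")`).
#' @param predicted_deleterious Optional precomputed deleteriousness flag
#'   (used for missense only).
#' @param driver_role Driver annotation of the gene
#'   (`ONCOGENE`/`TSG`/`BOTH`/`NONE`).
#' @param config Configuration list.
#' @return Impact score in `[0, 1]`.
#' @export
consequence_impact <- function(term, predicted_deleterious = FALSE,
                               driver_role = "NONE",
                               config = default_config()) {
  cs <- config$variant_scoring$consequence
  if (is.na(term) || !nzchar(term)) term <- "other"
  if (!(term %in% CONSEQUENCE_TERMS)) {
    dr_abort(sprintf("unknown consequence term '%s'", term),
             "drugrank_argument_error")
  }
  score <- switch(term,
    frameshift = cs$frameshift,
    stop_gained = cs$stop_gained,
    splice = cs$splice,
    missense = if (isTRUE(predicted_deleterious)) cs$missense_deleterious
               else cs$missense,
    inframe_indel = cs$inframe_indel,
    synonymous = cs$synonymous,
    other = cs$other
  )
  truncating <- term %in% c("frameshift", "stop_gained", "splice")
  if (truncating && identical(driver_role, "ONCOGENE")) {
    score <- score * config$variant_scoring$oncogene_truncating_factor
  }
  score
}

#' Rarity term from the population allele frequency
#'
#' 1.0 when the frequency is absent or at most the rare bound (1e-4 by
#' default), 0.0 at or above the common bound (1e-2), log-linear in between;
#' monotone non-increasing.
#'
#' @param population_af Population allele frequency in `[0, 1]`, or `NA`.
#' @param config Configuration list.
#' @return Rarity score in `[0, 1]`.
#' @export
frequency_term <- function(population_af, config = default_config()) {
  if (is.null(population_af) || is.na(population_af)) return(1.0)
  if (population_af < 0 || population_af > 1) {
    dr_abort("population_af must lie in [0,1]", "drugrank_argument_error")
  }
  lo <- config$variant_scoring$af_rare
  hi <- config$variant_scoring$af_common
  if (population_af <= lo) return(1.0)
  if (population_af >= hi) return(0.0)
  1 - (log10(population_af) - log10(lo)) / (log10(hi) - log10(lo))
}

# Per-alteration impact scores for one profile entry: somatic variants via
# the consequence table (down-weighted if subclonal), CNV / expression /
# assumed alterations via the fixed mapping. Returns a named numeric vector
# (possibly empty). Neutral expression contributes nothing.
#' Per-alteration impact inputs for a gene
#'
#' Maps every actionable alteration of a profile entry onto the common
#' `[0, 1]` impact scale used by the gene-score consequence component:
#' somatic variants through [consequence_impact()] (times a subclonal
#' factor when the VAF is below the subclonal cutoff), copy-number and
#' expression alterations through fixed driver-role-aware mappings, and
#' gene-list entries as assumed-altered.
#'
#' @param entry A per-gene entry from a `patient_profile`.
#' @param annotation A single-row slice of the knowledge base's
#'   `gene_annotations` table, or `NULL` for an unannotated gene.
#' @param config Configuration list.
#' @return Named numeric vector of impact scores (empty when the gene
#'   carries no actionable alteration).
#' @export
alteration_inputs <- function(entry, annotation = NULL,
                              config = default_config()) {
  vs <- config$variant_scoring
  role <- if (!is.null(annotation) && nrow(annotation))
    annotation$driver_role[1] else "NONE"
  impacts <- numeric(0)

  if (nrow(entry$somatic)) {
    for (i in seq_len(nrow(entry$somatic))) {
      v <- entry$somatic[i, ]
      imp <- consequence_impact(v$consequence,
                                isTRUE(v$predicted_deleterious), role, config)
      if (!is.na(v$vaf) && v$vaf < vs$subclonal_vaf) {
        imp <- imp * vs$subclonal_factor
      }
      impacts <- c(impacts, setNames(imp, sprintf("SNV:%s:%s:%s>%s",
                                                  v$chrom, v$pos, v$ref,
                                                  v$alt)))
    }
  }
  ai <- vs$alteration_impact
  if (!is.na(entry$cnv)) {
    imp <- if (entry$cnv == "AMP") {
      if (role %in% c("ONCOGENE", "BOTH")) ai$amp_oncogene else ai$amp_other
    } else {
      if (role %in% c("TSG", "BOTH")) ai$del_tsg else ai$del_other
    }
    impacts <- c(impacts, setNames(imp, paste0("CNV:", entry$cnv)))
  }
  if (entry$expr_class %in% c("OVER", "UNDER")) {
    concordant <- (entry$expr_class == "OVER" &&
                     role %in% c("ONCOGENE", "BOTH")) ||
                  (entry$expr_class == "UNDER" && role %in% c("TSG", "BOTH"))
    imp <- if (concordant) ai$expr_concordant else ai$expr_discordant
    impacts <- c(impacts, setNames(imp, paste0("EXPR:", entry$expr_class)))
  }
  if (isTRUE(entry$assumed)) {
    impacts <- c(impacts, setNames(ai$assumed, "ASSUMED"))
  }
  impacts
}

# Alteration tokens exhibited by a profile entry, used to match the
# required_alteration / context_alteration grammar. An assumed-altered
# gene (bare gene-list query) matches every token.
alteration_tokens <- function(entry, annotation = NULL,
                              config = default_config()) {
  role <- if (!is.null(annotation) && nrow(annotation))
    annotation$driver_role[1] else "NONE"
  tokens <- character(0)
  if (nrow(entry$somatic)) {
    tokens <- c(tokens, "SNV")
    raw <- vapply(seq_len(nrow(entry$somatic)), function(i) {
      v <- entry$somatic[i, ]
      consequence_impact(v$consequence, isTRUE(v$predicted_deleterious),
                         role, config)
    }, numeric(1))
    if (any(raw >= config$variant_scoring$oncogenic_snv_min_impact)) {
      tokens <- c(tokens, "ONCOGENIC_SNV")
    }
  }
  if (!is.na(entry$cnv)) tokens <- c(tokens, entry$cnv)
  if (entry$expr_class == "OVER") tokens <- c(tokens, "OVEREXPR")
  if (entry$expr_class == "UNDER") tokens <- c(tokens, "UNDEREXPR")
  if (isTRUE(entry$assumed)) tokens <- c(tokens, "ASSUMED")
  tokens
}

matches_required <- function(tokens, required) {
  if (length(tokens) == 0) return(FALSE)
  if ("ASSUMED" %in% tokens) return(TRUE)
  switch(required,
    ANY = TRUE,
    SNV = any(c("SNV", "ONCOGENIC_SNV") %in% tokens),
    required %in% tokens
  )
}
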