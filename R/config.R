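#' Default scoring configuration
#'
#' Every numeric constant used by the scoring engines lives here and can be
#' overridden through [load_config()]. Values are the package's documented
#' defaults; see the methods vignette for the rationale behind each.
#'
#' Blocks:
#' \describe{
#'   \item{variant_scoring}{per-consequence impact table, oncogene
#'     truncation down-weight, subclonal VAF handling, population-frequency
#'     interpolation bounds, and the impact mapping for CNV / expression /
#'     gene-list alterations.}
#'   \item{expression}{percentile cutoffs for OVER / UNDER calls.}
#'   \item{gscore}{component weights (sum to 1), druggability and clinical
#'     evidence ladders, off-tumor penalty, concordance bonus schedule.}
#'   \item{dscore}{component weights (sum to 1), clinical-status ladder,
#'     indication ladder, association-class ladder, source-count saturation.}
#'   \item{prioritizer}{dependency / pathway GScore decay, pathway depth,
#'     BTC thresholds (strict inequalities).}
#' }
#'
#' @return A nested list of configuration values.
#' @export
default_config <- function() {
  list(
    variant_scoring = list(
      consequence = list(
        frameshift = 1.0, stop_gained = 1.0, splice = 1.0,
        missense_deleterious = 0.8, missense = 0.5,
        inframe_indel = 0.6, synonymous = 0.0, other = 0.0
      ),
      oncogene_truncating_factor = 0.5,
      subclonal_vaf = 0.05,
      subclonal_factor = 0.8,
      af_rare = 1e-4,
      af_common = 1e-2,
      alteration_impact = list(
        amp_oncogene = 0.9, amp_other = 0.4,
        del_tsg = 0.9, del_other = 0.4,
        expr_concordant = 0.7, expr_discordant = 0.2,
        assumed = 0.8
      ),
      oncogenic_snv_min_impact = 0.8
    ),
    expression = list(over_percentile = 0.90, under_percentile = 0.10),
    gscore = list(
      weights = c(consequence = 0.25, frequency = 0.10, essentiality = 0.15,
                  druggability = 0.25, clinical = 0.25),
      druggability_ladder = c(DIRECT_TARGET = 1.0, BIOMARKER = 0.75,
                              GENETIC_DEPENDENCY = 0.5, PATHWAY_MEMBER = 0.25,
                              NONE = 0.0),
      clinical_ladder = c(APPROVED_BIOMARKER = 1.0, LATE_TRIALS = 0.75,
                          EARLY_TRIALS = 0.5, PRECLINICAL = 0.25, NONE = 0.0),
      off_tumor_penalty = 0.75,
      concordance_bonus = c(two_channels = 0.1, three_channels = 0.2)
    ),
    dscore = list(
      weights = c(status = 0.35, indication = 0.20, association = 0.20,
                  support = 0.10, collective = 0.15),
      status_ladder = c(APPROVED = 1.0, CLINICAL_TRIAL = 0.6,
                        EXPERIMENTAL = 0.2),
      indication_ladder = c(match = 1.0, other_cancer = 0.5,
                            non_cancer = 0.25),
      association_ladder = c(DIRECT_TARGET = 1.0, BIOMARKER = 0.9,
                             GENETIC_DEPENDENCY = 0.7, PATHWAY_MEMBER = 0.5),
      support_saturation = 5
    ),
    prioritizer = list(
      dependency_decay = 0.9,
      pathway_decay = 0.75,
      max_depth = 3,
      btc_gscore = 0.6,
      btc_dscore = 0.7
    )
  )
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it recursively over [default_config()]:
#' any value present in the file replaces the default, everything else is
#' kept. `load_config(NULL)` returns the defaults.
#'
#' @param path Path to a YAML configuration file, or `NULL`.
#' @return A configuration list as [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) dr_abort(sprintf("config file not found: %s", path),
                                   "drugrank_config_error")
  user <- yaml::read_yaml(path)
  merge_config(cfg, user)
}

merge_config <- function(base, override) {
  if (!is.list(override)) return(override)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else if (is.numeric(base[[nm]]) && !is.null(names(base[[nm]])) &&
               is.list(override[[nm]])) {
      # YAML maps arrive as lists; fold back into the named numeric vector
      v <- base[[nm]]
      v[names(override[[nm]])] <- unlist(override[[nm]])
      base[[nm]] <- v
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

check_weights <- function(weights, what) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    dr_abort(sprintf("%s weights must be non-negative and sum to 1 (got %s)",
                     what, format(sum(weights), digits = 12)),
             "drugrank_config_error")
  }
  invisible(weights)
}
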