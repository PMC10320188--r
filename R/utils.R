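`%||%` <- function(x, y) if (is.null(x)) y else x

# classed error helper so callers can distinguish schema / integrity /
# format / config failures programmatically
dr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "drugrank_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Controlled cancer-type vocabulary
#'
#' Flat list of organ-level cancer-type codes used throughout the package
#' (drug indications, gene clinical annotations, queries). `PAN_CANCER`
#' matches any queried type; queries may also use `"ALL"` to expand the drug
#' search across all cancer indications.
#'
#' @return Character vector of valid codes.
#' @export
cancer_type_codes <- function() {
  c("SKIN", "BREAST", "LUNG", "COLON", "KIDNEY", "BLOOD", "PROSTATE",
    "PAN_CANCER")
}

CLINICAL_STATUS  <- c("APPROVED", "CLINICAL_TRIAL", "EXPERIMENTAL")
THERAPY_TYPES    <- c("TARGETED", "CHEMOTHERAPY", "HORMONAL", "IMMUNOTHERAPY",
                      "OTHER")
ASSOCIATION_TYPES <- c("DIRECT_TARGET", "BIOMARKER")
RESPONSES        <- c("SENSITIVITY", "RESISTANCE")
DRIVER_ROLES     <- c("ONCOGENE", "TSG", "BOTH", "NONE")
CLINICAL_LEVELS  <- c("APPROVED_BIOMARKER", "LATE_TRIALS", "EARLY_TRIALS",
                      "PRECLINICAL", "NONE")
ALTERATION_TOKENS <- c("SNV", "ONCOGENIC_SNV", "AMP", "DEL", "OVEREXPR",
                       "UNDEREXPR", "ANY")
EVIDENCE_CLASSES <- c("DIRECT_TARGET", "BIOMARKER", "GENETIC_DEPENDENCY",
                      "PATHWAY_MEMBER")
FUNCTION_EFFECTS <- c("NO_FUNCTION", "DECREASED", "NORMAL")
ZYGOSITIES       <- c("HET", "HOM", "ANY")
PGX_LABELS       <- c("STRONGLY_NOT_RECOMMENDED", "MODERATELY_RECOMMENDED",
                      "STANDARD")
CONSEQUENCE_TERMS <- c("frameshift", "stop_gained", "missense", "splice",
                       "inframe_indel", "synonymous", "other")

#' Normalize a drug name
#'
#' Uppercases, trims, and collapses internal whitespace. Combination drugs
#' are encoded as a single entry whose name joins components with `" + "`.
#'
#' @param x Character vector of drug names.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

normalize_gene <- function(x) toupper(trimws(x))

# comma-joined multi-valued cells (indications, cancer types, drug sets)
split_multi <- function(x) {
  out <- strsplit(as.character(x), ",", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_multi <- function(x) vapply(x, paste, character(1), collapse = ",")
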