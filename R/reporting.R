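# Two-section genomic report: (1) run summary and statistical overview,
# (2) the complete Best-Therapeutic-Candidate list with its annotations.

#' Summarize a completed run
#'
#' Counts are derived solely from the inputs and the ranked table, so the
#' summary is recomputable from them.
#'
#' @param table Ranked results table of a `drug_ranking`.
#' @param profile The queried `patient_profile`.
#' @param options List with `mode` and `cancer_type` as used for the run.
#' @param kb_version Knowledge-base version tag.
#' @param config Configuration list (echoed as a weight digest).
#' @return A `run_summary` list.
#' @export
summarize <- function(table, profile, options, kb_version = "unversioned",
                      config = default_config()) {
  digest <- paste(
    paste0("g:", paste(names(config$gscore$weights),
                       config$gscore$weights, sep = "=", collapse = ",")),
    paste0("d:", paste(names(config$dscore$weights),
                       config$dscore$weights, sep = "=", collapse = ",")),
    sep = ";")
  structure(
    list(
      n_somatic_variants = unname(profile$input_counts[["somatic"]]),
      n_germline_variants = unname(profile$input_counts[["germline"]]),
      n_cnv_records = unname(profile$input_counts[["cnv"]]),
      n_expression_records = unname(profile$input_counts[["expression"]]),
      n_gene_list = unname(profile$input_counts[["gene_list"]]),
      n_altered_genes = length(altered_genes(profile)),
      n_candidate_drugs = length(unique(table$drug_id)),
      n_rows = nrow(table),
      n_btc = sum(table$is_btc),
      mode = options$mode,
      cancer_type = options$cancer_type,
      kb_version = kb_version,
      weight_digest = digest
    ),
    class = "run_summary"
  )
}

btc_report_fields <- function(btc_rows) {
  if (nrow(btc_rows) == 0) {
    return(data.frame(drug = character(0), approval_status = character(0),
                      therapy_type = character(0), response = character(0),
                      drug_family = character(0),
                      actionable_variants = character(0),
                      association_type = character(0),
                      gscore = numeric(0), dscore = numeric(0),
                      pgx_label = character(0), stringsAsFactors = FALSE))
  }
  icons <- vapply(seq_len(nrow(btc_rows)), function(i) {
    r <- btc_rows[i, ]
    flags <- c(if (r$has_snv) "SNV",
               if (!is.na(r$cnv_status)) r$cnv_status,
               if (r$expr_class %in% c("OVER", "UNDER")) r$expr_class,
               if (r$has_germline) "GERMLINE")
    paste0(r$gene, if (length(flags)) paste0(" [", paste(flags, collapse = ","),
                                             "]") else "")
  }, character(1))
  data.frame(drug = btc_rows$drug_name,
             approval_status = btc_rows$clinical_status,
             therapy_type = btc_rows$therapy_type,
             response = btc_rows$response,
             drug_family = btc_rows$family,
             actionable_variants = icons,
             association_type = btc_rows$evidence_class,
             gscore = btc_rows$gscore, dscore = btc_rows$dscore,
             pgx_label = btc_rows$pgx_label, stringsAsFactors = FALSE)
}

#' Render the genomic report
#'
#' Exactly two sections, in order: (1) summary and statistical overview of
#' the run, (2) the complete list of Best Therapeutic Candidates annotated
#' with approval status, therapy type, response, drug family, actionable
#' variants and drug-gene association type. Rendering is deterministic:
#' the same run produces byte-identical output.
#'
#' @param summary A `run_summary` from [summarize()].
#' @param btc_rows BTC subset of the ranked table.
#' @param format `"markdown"` or `"json"`.
#' @return A single character string (the document).
#' @export
render_report <- function(summary, btc_rows,
                          format = c("markdown", "json")) {
  if (length(format) == 1 && !(format %in% c("markdown", "json"))) {
    dr_abort(sprintf("unknown report format '%s'", format),
             "drugrank_argument_error")
  }
  format <- match.arg(format)
  fields <- btc_report_fields(btc_rows)
  if (format == "json") {
    doc <- list(summary = unclass(summary),
                best_therapeutic_candidates = fields)
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, na = "null")))
  }
  lines <- c(
    "# Genomic report",
    "",
    "## 1. Summary",
    "",
    sprintf("- Query mode: %s; cancer type: %s", summary$mode,
            summary$cancer_type),
    sprintf("- Knowledge base: %s", summary$kb_version),
    sprintf("- Input records: %d somatic, %d germline, %d CNV, %d expression, %d gene-list",
            summary$n_somatic_variants, summary$n_germline_variants,
            summary$n_cnv_records, summary$n_expression_records,
            summary$n_gene_list),
    sprintf("- Altered genes: %d", summary$n_altered_genes),
    sprintf("- Candidate drugs: %d (%d ranked drug-gene associations)",
            summary$n_candidate_drugs, summary$n_rows),
    sprintf("- Best Therapeutic Candidates: %d", summary$n_btc),
    "",
    "## 2. Best therapeutic candidates",
    ""
  )
  if (nrow(fields) == 0) {
    lines <- c(lines, "No Best Therapeutic Candidates were identified.")
  } else {
    header <- "| Drug | Status | Therapy | Response | Family | Actionable variants | Association | GScore | DScore | PGx |"
    sep <- "|---|---|---|---|---|---|---|---|---|---|"
    body <- vapply(seq_len(nrow(fields)), function(i) {
      r <- fields[i, ]
      sprintf("| %s | %s | %s | %s | %s | %s | %s | %.3f | %.3f | %s |",
              r$drug, r$approval_status, r$therapy_type, r$response,
              r$drug_family, r$actionable_variants, r$association_type,
              r$gscore, r$dscore,
              if (is.na(r$pgx_label)) "-" else r$pgx_label)
    }, character(1))
    lines <- c(lines, header, sep, body)
  }
  paste(c(lines, ""), collapse = "\n")
}
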