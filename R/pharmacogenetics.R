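# Simplified CPIC-style pharmacogenetic rules engine: single-variant +
# zygosity matching of germline variants, producing per-drug usage labels
# that annotate (never re-rank) the results table.

pgx_severity <- function(label) {
  match(label, c("STANDARD", "MODERATELY_RECOMMENDED",
                 "STRONGLY_NOT_RECOMMENDED"))
}

zygosity_satisfied <- function(observed, required) {
  switch(required,
    ANY = TRUE,
    HET = observed %in% c("HET", "HOM"),  # HOM is stronger evidence
    HOM = observed == "HOM",
    FALSE
  )
}

#' Match germline variants against pharmacogenetic rules
#'
#' A rule fires when its variant key (`chrom:pos:ref:alt`) matches a
#' germline variant and the observed zygosity satisfies the rule's
#' requirement (a homozygous call satisfies a heterozygous requirement).
#' One recommendation is kept per (drug, gene), resolving conflicts by
#' severity: strongly-not-recommended > moderately-recommended > standard.
#' Output is independent of variant input order.
#'
#' @param germline_variants Variant data frame from [parse_vcf()] (origin
#'   `GERMLINE`).
#' @param rules The `pgx_rules` table of a [knowledge_base()].
#' @return Data frame with columns `drug_id, gene, label, variant_key,
#'   zygosity` (zero rows when nothing matches).
#' @export
match_pgx <- function(germline_variants, rules) {
  out <- data.frame(drug_id = character(0), gene = character(0),
                    label = character(0), variant_key = character(0),
                    zygosity = character(0), stringsAsFactors = FALSE)
  if (is.null(germline_variants) || nrow(germline_variants) == 0 ||
      is.null(rules) || nrow(rules) == 0) {
    return(out)
  }
  keys <- sprintf("%s:%d:%s:%s", germline_variants$chrom,
                  germline_variants$pos, germline_variants$ref,
                  germline_variants$alt)
  hits <- list()
  for (i in seq_len(nrow(rules))) {
    j <- which(keys == rules$variant_key[i])
    if (length(j) == 0) next
    # one variant record per key; take the strongest observed zygosity
    zyg <- germline_variants$genotype[j]
    observed <- if ("HOM" %in% zyg) "HOM" else if ("HET" %in% zyg) "HET"
                else "UNKNOWN"
    ok <- zygosity_satisfied(observed, rules$zygosity_required[i])
    if (!ok) next
    for (drug in split_multi(rules$affected_drugs[i])[[1]]) {
      hits[[length(hits) + 1L]] <- data.frame(
        drug_id = drug, gene = rules$gene[i], label = rules$label[i],
        variant_key = rules$variant_key[i], zygosity = observed,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(out)
  rec <- do.call(rbind, hits)
  # most severe label per (drug, gene); deterministic tie-break on key
  rec <- rec[order(rec$drug_id, rec$gene, -pgx_severity(rec$label),
                   rec$variant_key, method = "radix"), ]
  rec <- rec[!duplicated(rec[, c("drug_id", "gene")]), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Annotate ranked rows with pharmacogenetic labels
#'
#' Fills the `pgx_label` column where the row's drug matches a
#' recommendation (most severe across genes); ranking order is never
#' changed and the operation is idempotent. Recommendations for drugs
#' absent from the table are ignored.
#'
#' @param rows Ranked results table.
#' @param recommendations Output of [match_pgx()].
#' @return `rows` with a `pgx_label` column (`NA` where no rule fired).
#' @export
annotate_rows <- function(rows, recommendations) {
  rows$pgx_label <- rep(NA_character_, nrow(rows))
  if (nrow(rows) == 0 || is.null(recommendations) ||
      nrow(recommendations) == 0) {
    return(rows)
  }
  rec <- recommendations[order(recommendations$drug_id,
                               -pgx_severity(recommendations$label),
                               method = "radix"), ]
  rec <- rec[!duplicated(rec$drug_id), , drop = FALSE]
  idx <- match(rows$drug_id, rec$drug_id)
  rows$pgx_label <- rec$label[idx]
  rows
}
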