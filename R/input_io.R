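# Patient-side input parsing: VCF (small variants), two-column CNV TSV,
# GSEA-style RNK expression ranking, plain gene list; merged into a
# per-gene patient profile.

variant_columns <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), origin = character(0),
             genotype = character(0), vaf = numeric(0), gene = character(0),
             consequence = character(0), predicted_deleterious = logical(0),
             population_af = numeric(0), stringsAsFactors = FALSE)
}

info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$|=)"), info)
}

#' Parse small variants from a VCF file
#'
#' Reads a VCF 4.x file and returns one record per ALT allele (multiallelic
#' sites are split). Genotype (HET / HOM / UNKNOWN) is derived from the
#' first sample's `GT`; the variant allele fraction from `AD` when present.
#' Pre-annotated gene / consequence information is read from the INFO keys
#' `GENE`, `CONSEQUENCE`, `DELETERIOUS` (flag) and `POPAF` (population
#' allele frequency); unannotated records carry `NA` in those columns.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @param origin `"SOMATIC"` or `"GERMLINE"`; stamped on every record.
#' @return A data frame of variant records (one row per ALT allele) with
#'   columns `chrom, pos, ref, alt, origin, genotype, vaf, gene,
#'   consequence, predicted_deleterious, population_af`.
#' @export
parse_vcf <- function(path, origin = c("SOMATIC", "GERMLINE")) {
  origin <- match.arg(origin)
  if (!file.exists(path)) {
    dr_abort(sprintf("VCF file not found: %s", path), "drugrank_io_error")
  }
  header_probe <- readLines(path, n = 1000L, warn = FALSE)
  if (!any(startsWith(header_probe, "#CHROM"))) {
    dr_abort(sprintf("not a VCF file (no #CHROM header line): %s", path),
             "drugrank_format_error")
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) return(variant_columns())
  gt <- vcf@gt
  has_sample <- !is.null(gt) && ncol(gt) >= 2

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- fix[i, "INFO"] %||% ""
    if (is.na(info)) info <- ""
    gene <- info_field(info, "GENE")
    consequence <- info_field(info, "CONSEQUENCE")
    deleterious <- info_flag(info, "DELETERIOUS")
    popaf <- suppressWarnings(as.numeric(info_field(info, "POPAF")))

    alleles <- character(0); ad <- numeric(0)
    if (has_sample && !is.na(gt[i, 1]) && !is.na(gt[i, 2])) {
      keys <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
      vals <- strsplit(gt[i, 2], ":", fixed = TRUE)[[1]]
      gt_str <- vals[match("GT", keys)]
      ad_str <- vals[match("AD", keys)]
      if (!is.na(gt_str)) alleles <- strsplit(gt_str, "[/|]")[[1]]
      if (!is.na(ad_str)) {
        ad <- suppressWarnings(as.numeric(strsplit(ad_str, ",",
                                                   fixed = TRUE)[[1]]))
      }
    }
    rows <- lapply(seq_along(alts), function(k) {
      code <- as.character(k)
      genotype <- "UNKNOWN"
      if (length(alleles) && !any(alleles == ".")) {
        if (all(alleles == code)) genotype <- "HOM"
        else if (any(alleles == code)) genotype <- "HET"
      }
      vaf <- NA_real_
      if (length(ad) > k && !anyNA(ad) && sum(ad) > 0) {
        vaf <- ad[k + 1] / sum(ad)
      }
      data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                 ref = fix[i, "REF"], alt = alts[k], origin = origin,
                 genotype = genotype, vaf = vaf,
                 gene = if (is.na(gene)) NA_character_ else normalize_gene(gene),
                 consequence = consequence,
                 predicted_deleterious = deleterious,
                 population_af = popaf, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse gene-level CNV calls from a two-column TSV
#'
#' Accepts `gene<TAB>status` rows with status `AMP` or `DEL`
#' (case-insensitive); `#` comment lines and an optional header row are
#' ignored. A duplicated gene keeps the last status seen, with a warning.
#'
#' @param path Path to the CNV TSV.
#' @return Data frame with columns `gene`, `status`.
#' @export
parse_cnv_tsv <- function(path) {
  if (!file.exists(path)) {
    dr_abort(sprintf("CNV file not found: %s", path), "drugrank_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  genes <- character(0); status <- character(0)
  first_data <- TRUE
  for (idx in keep) {
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      dr_abort(sprintf("CNV file line %d: expected 2 tab-separated columns",
                       idx), "drugrank_format_error")
    }
    st <- toupper(trimws(fields[2]))
    if (!(st %in% c("AMP", "DEL"))) {
      if (first_data) { first_data <- FALSE; next }  # header row
      dr_abort(sprintf("CNV file line %d: unknown status '%s' (expected AMP or DEL)",
                       idx, fields[2]), "drugrank_format_error")
    }
    first_data <- FALSE
    genes <- c(genes, normalize_gene(fields[1]))
    status <- c(status, st)
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning(sprintf("duplicated CNV gene(s), keeping last status: %s",
                    paste(dups, collapse = ", ")))
    keep_last <- !duplicated(genes, fromLast = TRUE)
    # preserve file order of the surviving records
    genes <- genes[keep_last]; status <- status[keep_last]
  }
  data.frame(gene = genes, status = status, stringsAsFactors = FALSE)
}

#' Parse a gene-expression ranking (RNK) file
#'
#' Two tab-separated columns: gene symbol and a signed ranking metric
#' (GSEA `.rnk` convention); `#` comment lines are ignored. A duplicated
#' gene keeps the value with the largest absolute magnitude, with a warning.
#'
#' @param path Path to the RNK file.
#' @return Data frame with columns `gene`, `rank_value`.
#' @export
parse_rnk <- function(path) {
  if (!file.exists(path)) {
    dr_abort(sprintf("RNK file not found: %s", path), "drugrank_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  genes <- character(0); vals <- numeric(0)
  for (idx in keep) {
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      dr_abort(sprintf("RNK file line %d: expected 2 tab-separated columns",
                       idx), "drugrank_format_error")
    }
    v <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(v) || !is.finite(v)) {
      dr_abort(sprintf("RNK file line %d: non-numeric score '%s'", idx,
                       fields[2]), "drugrank_format_error")
    }
    genes <- c(genes, normalize_gene(fields[1])); vals <- c(vals, v)
  }
  if (anyDuplicated(genes)) {
    warning(sprintf("duplicated RNK gene(s), keeping most extreme value: %s",
                    paste(unique(genes[duplicated(genes)]), collapse = ", ")))
    keep_rows <- vapply(unique(genes), function(g) {
      rows <- which(genes == g)
      rows[which.max(abs(vals[rows]))]
    }, integer(1))
    keep_rows <- sort(keep_rows)
    genes <- genes[keep_rows]; vals <- vals[keep_rows]
  }
  data.frame(gene = genes, rank_value = vals, stringsAsFactors = FALSE)
}

#' Parse a plain gene-list file
#'
#' One symbol per line; output is uppercased, de-duplicated, and
#' order-preserving.
#'
#' @param path Path to the gene list.
#' @return Character vector of gene symbols.
#' @export
parse_gene_list <- function(path) {
  if (!file.exists(path)) {
    dr_abort(sprintf("gene list not found: %s", path), "drugrank_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_gene(lines))
}

empty_profile_entry <- function(gene) {
  list(gene = gene, somatic = variant_columns(), germline = variant_columns(),
       cnv = NA_character_, expr_class = "ABSENT",
       expr_percentile = NA_real_, assumed = FALSE)
}

#' Merge patient inputs into a per-gene profile
#'
#' Combines somatic/germline variant records, CNV calls, an expression
#' ranking and/or a bare gene list into a `patient_profile`: a per-gene map
#' of alteration evidence keyed by normalized symbol. Expression class is
#' derived from the gene's percentile within the supplied ranking (`OVER`
#' at or above the upper cutoff, `UNDER` at or below the lower, else
#' `NEUTRAL`). Genes supplied via the bare list enter as assumed-altered.
#'
#' @param somatic,germline Variant data frames from [parse_vcf()].
#' @param cnv Data frame from [parse_cnv_tsv()].
#' @param expr Data frame from [parse_rnk()].
#' @param genes Character vector from [parse_gene_list()].
#' @param cancer_type Queried cancer-type code (see [cancer_type_codes()])
#'   or `"ALL"`.
#' @param mode `"CLINICAL"` or `"DISCOVERY"`.
#' @param config Configuration list, see [default_config()].
#' @return A `patient_profile` object.
#' @export
build_profile <- function(somatic = NULL, germline = NULL, cnv = NULL,
                          expr = NULL, genes = NULL, cancer_type = "ALL",
                          mode = c("CLINICAL", "DISCOVERY"),
                          config = default_config()) {
  mode <- match.arg(mode)
  if (!(cancer_type %in% c(cancer_type_codes(), "ALL"))) {
    dr_abort(sprintf("unknown cancer type '%s'; valid codes: %s, ALL",
                     cancer_type, paste(cancer_type_codes(), collapse = ", ")),
             "drugrank_argument_error")
  }
  n_in <- sum(NROW(somatic), NROW(germline), NROW(cnv), NROW(expr),
              length(genes))
  if (n_in == 0) {
    dr_abort("empty query: supply at least one non-empty input channel",
             "drugrank_empty_query_error")
  }

  entries <- list()
  get_entry <- function(g) entries[[g]] %||% empty_profile_entry(g)

  add_variants <- function(df, slot) {
    if (is.null(df) || nrow(df) == 0) return()
    df$gene <- normalize_gene(df$gene)
    unmapped <- sum(is.na(df$gene) | !nzchar(df$gene))
    if (unmapped > 0) {
      warning(sprintf("%d %s variant(s) without a gene symbol were dropped",
                      unmapped, tolower(slot)))
    }
    df <- df[!is.na(df$gene) & nzchar(df$gene), , drop = FALSE]
    for (g in unique(df$gene)) {
      e <- get_entry(g)
      e[[slot]] <- rbind(e[[slot]], df[df$gene == g, , drop = FALSE])
      rownames(e[[slot]]) <- NULL
      entries[[g]] <<- e
    }
  }
  add_variants(somatic, "somatic")
  add_variants(germline, "germline")

  if (!is.null(cnv) && nrow(cnv)) {
    cnv$gene <- normalize_gene(cnv$gene)
    cnv <- cnv[!duplicated(cnv$gene, fromLast = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(cnv))) {
      e <- get_entry(cnv$gene[i])
      e$cnv <- cnv$status[i]
      entries[[cnv$gene[i]]] <- e
    }
  }

  if (!is.null(expr) && nrow(expr)) {
    expr$gene <- normalize_gene(expr$gene)
    pct <- rank(expr$rank_value, ties.method = "average") / nrow(expr)
    hi <- config$expression$over_percentile
    lo <- config$expression$under_percentile
    for (i in seq_len(nrow(expr))) {
      e <- get_entry(expr$gene[i])
      e$expr_percentile <- pct[i]
      e$expr_class <- if (pct[i] >= hi) "OVER"
                      else if (pct[i] <= lo) "UNDER" else "NEUTRAL"
      entries[[expr$gene[i]]] <- e
    }
  }

  for (g in normalize_gene(genes %||% character(0))) {
    e <- get_entry(g)
    e$assumed <- TRUE
    entries[[g]] <- e
  }

  structure(
    list(genes = entries[order(names(entries))], cancer_type = cancer_type,
         mode = mode,
         input_counts = c(somatic = NROW(somatic), germline = NROW(germline),
                          cnv = NROW(cnv), expression = NROW(expr),
                          gene_list = length(genes %||% character(0)))),
    class = "patient_profile"
  )
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile>", length(x$genes), "gene(s);",
      "cancer_type =", x$cancer_type, "; mode =", x$mode, "\n")
  invisible(x)
}

# genes carrying at least one actionable alteration (germline variants
# inform pharmacogenetics only)
is_altered_entry <- function(e) {
  nrow(e$somatic) > 0 || !is.na(e$cnv) ||
    e$expr_class %in% c("OVER", "UNDER") || isTRUE(e$assumed)
}

altered_genes <- function(profile) {
  names(profile$genes)[vapply(profile$genes, is_altered_entry, logical(1))]
}
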