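# Knowledge-base schema: six tabular slots plus a version tag.
#
# drugs:            drug_id, name, family, clinical_status, indications,
#                   therapy_type
# associations:     drug_id, gene, association_type, response, n_sources,
#                   required_alteration
# gene_annotations: gene, driver_role, essentiality, clinical_level,
#                   clinical_cancer_types
# dependencies:     context_gene, context_alteration, dependent_gene
# pathway_edges:    upstream_gene, downstream_gene
# pgx_rules:        gene, variant_key, function_effect, zygosity_required,
#                   affected_drugs, label
#
# Multi-valued cells (indications, clinical_cancer_types, affected_drugs)
# are comma-joined strings; an empty indications cell means a non-cancer
# indication.

KB_SCHEMA <- list(
  drugs = c("drug_id", "name", "family", "clinical_status", "indications",
            "therapy_type"),
  associations = c("drug_id", "gene", "association_type", "response",
                   "n_sources", "required_alteration"),
  gene_annotations = c("gene", "driver_role", "essentiality",
                       "clinical_level", "clinical_cancer_types"),
  dependencies = c("context_gene", "context_alteration", "dependent_gene"),
  pathway_edges = c("upstream_gene", "downstream_gene"),
  pgx_rules = c("gene", "variant_key", "function_effect", "zygosity_required",
                "affected_drugs", "label")
)

empty_kb_table <- function(name) {
  cols <- KB_SCHEMA[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  if (name == "associations") df$n_sources <- integer(0)
  if (name == "gene_annotations") df$essentiality <- numeric(0)
  df
}

#' Construct and validate a knowledge base
#'
#' Assembles the six tables of the drug-gene knowledge base into a
#' `knowledge_base` object and runs full validation: enum membership,
#' uniqueness constraints, value ranges, and referential integrity (every
#' association, dependency, pathway edge and pharmacogenetic rule must
#' resolve to existing drug / gene rows).
#'
#' @param drugs,associations,gene_annotations,dependencies,pathway_edges,pgx_rules
#'   Data frames following the documented schema; missing arguments default
#'   to empty tables.
#' @param version Free-text version tag carried through write/load.
#' @return A validated `knowledge_base` object.
#' @export
knowledge_base <- function(drugs = empty_kb_table("drugs"),
                           associations = empty_kb_table("associations"),
                           gene_annotations = empty_kb_table("gene_annotations"),
                           dependencies = empty_kb_table("dependencies"),
                           pathway_edges = empty_kb_table("pathway_edges"),
                           pgx_rules = empty_kb_table("pgx_rules"),
                           version = "unversioned") {
  kb <- structure(
    list(drugs = drugs, associations = associations,
         gene_annotations = gene_annotations, dependencies = dependencies,
         pathway_edges = pathway_edges, pgx_rules = pgx_rules,
         version = version),
    class = "knowledge_base"
  )
  validate_kb(kb)
  kb
}

check_columns <- function(df, name) {
  missing <- setdiff(KB_SCHEMA[[name]], names(df))
  if (length(missing)) {
    dr_abort(sprintf("table '%s' is missing column(s): %s", name,
                     paste(missing, collapse = ", ")),
             "drugrank_schema_error")
  }
  df[, KB_SCHEMA[[name]], drop = FALSE]
}

check_enum <- function(values, allowed, table, column) {
  bad <- which(!(values %in% allowed))
  if (length(bad)) {
    dr_abort(sprintf("table '%s', column '%s': invalid value '%s' at row %d (allowed: %s)",
                     table, column, values[bad[1]], bad[1],
                     paste(allowed, collapse = ", ")),
             "drugrank_schema_error")
  }
  invisible(values)
}

check_multi_enum <- function(cells, allowed, table, column) {
  for (i in seq_along(cells)) {
    bad <- setdiff(cells[[i]], allowed)
    if (length(bad)) {
      dr_abort(sprintf("table '%s', column '%s': invalid value '%s' at row %d",
                       table, column, bad[1], i),
               "drugrank_schema_error")
    }
  }
  invisible(cells)
}

validate_kb <- function(kb) {
  for (nm in names(KB_SCHEMA)) kb[[nm]] <- check_columns(kb[[nm]], nm)
  d <- kb$drugs; a <- kb$associations; g <- kb$gene_annotations
  dep <- kb$dependencies; pe <- kb$pathway_edges; px <- kb$pgx_rules

  check_enum(d$clinical_status, CLINICAL_STATUS, "drugs", "clinical_status")
  check_enum(d$therapy_type, THERAPY_TYPES, "drugs", "therapy_type")
  check_multi_enum(split_multi(d$indications), cancer_type_codes(),
                   "drugs", "indications")
  if (anyDuplicated(d$drug_id)) {
    dr_abort("table 'drugs': duplicated drug_id", "drugrank_schema_error")
  }
  if (anyDuplicated(normalize_drug_name(d$name))) {
    dr_abort("table 'drugs': duplicated normalized drug name",
             "drugrank_schema_error")
  }

  check_enum(a$association_type, ASSOCIATION_TYPES, "associations",
             "association_type")
  check_enum(a$response, RESPONSES, "associations", "response")
  check_enum(a$required_alteration, ALTERATION_TOKENS, "associations",
             "required_alteration")
  if (nrow(a) && (anyNA(a$n_sources) || any(a$n_sources < 1))) {
    dr_abort("table 'associations': n_sources must be >= 1",
             "drugrank_schema_error")
  }
  if (anyDuplicated(a[, c("drug_id", "gene", "association_type", "response")])) {
    dr_abort("table 'associations': duplicated (drug_id, gene, association_type, response)",
             "drugrank_schema_error")
  }

  check_enum(g$driver_role, DRIVER_ROLES, "gene_annotations", "driver_role")
  check_enum(g$clinical_level, CLINICAL_LEVELS, "gene_annotations",
             "clinical_level")
  check_multi_enum(split_multi(g$clinical_cancer_types), cancer_type_codes(),
                   "gene_annotations", "clinical_cancer_types")
  if (nrow(g) && (anyNA(g$essentiality) || any(g$essentiality < 0) ||
                  any(g$essentiality > 1))) {
    dr_abort("table 'gene_annotations': essentiality must lie in [0,1]",
             "drugrank_schema_error")
  }
  if (anyDuplicated(g$gene)) {
    dr_abort("table 'gene_annotations': duplicated gene",
             "drugrank_schema_error")
  }

  check_enum(dep$context_alteration, ALTERATION_TOKENS, "dependencies",
             "context_alteration")
  if (nrow(dep) && any(dep$context_gene == dep$dependent_gene)) {
    dr_abort("table 'dependencies': context_gene must differ from dependent_gene",
             "drugrank_schema_error")
  }
  if (nrow(pe) && any(pe$upstream_gene == pe$downstream_gene)) {
    dr_abort("table 'pathway_edges': self-loops are not allowed",
             "drugrank_schema_error")
  }

  check_enum(px$function_effect, FUNCTION_EFFECTS, "pgx_rules",
             "function_effect")
  check_enum(px$zygosity_required, ZYGOSITIES, "pgx_rules",
             "zygosity_required")
  check_enum(px$label, PGX_LABELS, "pgx_rules", "label")
  if (nrow(px) && any(lengths(split_multi(px$affected_drugs)) == 0)) {
    dr_abort("table 'pgx_rules': affected_drugs must be non-empty",
             "drugrank_schema_error")
  }

  # referential integrity
  dangle <- function(values, universe, table, column) {
    bad <- unique(setdiff(values, universe))
    if (length(bad)) {
      dr_abort(sprintf("table '%s', column '%s': unresolved reference(s): %s",
                       table, column, paste(bad, collapse = ", ")),
               "drugrank_integrity_error")
    }
  }
  dangle(a$drug_id, d$drug_id, "associations", "drug_id")
  dangle(a$gene, g$gene, "associations", "gene")
  dangle(dep$context_gene, g$gene, "dependencies", "context_gene")
  dangle(dep$dependent_gene, g$gene, "dependencies", "dependent_gene")
  dangle(pe$upstream_gene, g$gene, "pathway_edges", "upstream_gene")
  dangle(pe$downstream_gene, g$gene, "pathway_edges", "downstream_gene")
  dangle(px$gene, g$gene, "pgx_rules", "gene")
  dangle(unlist(split_multi(px$affected_drugs)), d$drug_id,
         "pgx_rules", "affected_drugs")
  invisible(kb)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>", x$version, "\n")
  cat(sprintf("  %d drugs, %d associations, %d genes, %d dependencies, %d pathway edges, %d pgx rules\n",
              nrow(x$drugs), nrow(x$associations), nrow(x$gene_annotations),
              nrow(x$dependencies), nrow(x$pathway_edges), nrow(x$pgx_rules)))
  invisible(x)
}

#' Load a knowledge base from a directory of TSV tables
#'
#' Expects the six files `drugs.tsv`, `associations.tsv`,
#' `gene_annotations.tsv`, `dependencies.tsv`, `pathway_edges.tsv`,
#' `pgx_rules.tsv` (UTF-8, header row, tab-separated, `#` comment lines
#' ignored; enums serialized as their names). The version tag is read from a
#' `# version=` comment at the top of `drugs.tsv`.
#'
#' @param path Directory containing the six tables.
#' @return A validated [knowledge_base()].
#' @export
load_knowledge_base <- function(path) {
  if (!dir.exists(path)) {
    dr_abort(sprintf("knowledge-base directory not found: %s", path),
             "drugrank_missing_table_error")
  }
  tables <- list()
  for (nm in names(KB_SCHEMA)) {
    file <- file.path(path, paste0(nm, ".tsv"))
    if (!file.exists(file)) {
      dr_abort(sprintf("missing knowledge-base table: %s", basename(file)),
               "drugrank_missing_table_error")
    }
    df <- utils::read.delim(file, sep = "\t", header = TRUE,
                            comment.char = "#", quote = "",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    # read.delim drops the all-comment case to 0 columns; normalize
    if (nrow(df) == 0 && ncol(df) == 0) df <- empty_kb_table(nm)
    df <- check_columns(df, nm)
    if (nm == "associations" && nrow(df)) {
      n <- suppressWarnings(as.integer(df$n_sources))
      if (anyNA(n)) {
        dr_abort(sprintf("table 'associations': non-integer n_sources at row %d",
                         which(is.na(n))[1]),
                 "drugrank_schema_error")
      }
      df$n_sources <- n
    } else if (nm == "associations") df$n_sources <- integer(0)
    if (nm == "gene_annotations" && nrow(df)) {
      e <- suppressWarnings(as.numeric(df$essentiality))
      if (anyNA(e)) {
        dr_abort(sprintf("table 'gene_annotations': non-numeric essentiality at row %d",
                         which(is.na(e))[1]),
                 "drugrank_schema_error")
      }
      df$essentiality <- e
    } else if (nm == "gene_annotations") df$essentiality <- numeric(0)
    rownames(df) <- NULL
    tables[[nm]] <- df
  }
  version <- "unversioned"
  head_lines <- readLines(file.path(path, "drugs.tsv"), n = 5L)
  vline <- grep("^#\\s*version=", head_lines, value = TRUE)
  if (length(vline)) version <- sub("^#\\s*version=\\s*", "", vline[1])
  knowledge_base(drugs = tables$drugs, associations = tables$associations,
                 gene_annotations = tables$gene_annotations,
                 dependencies = tables$dependencies,
                 pathway_edges = tables$pathway_edges,
                 pgx_rules = tables$pgx_rules, version = version)
}

#' Write a knowledge base to a directory of TSV tables
#'
#' Inverse of [load_knowledge_base()]: `load_knowledge_base(write_knowledge_base(kb, p))`
#' reproduces `kb` field for field.
#'
#' @param kb A [knowledge_base()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  validate_kb(kb)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    dr_abort(sprintf("cannot create directory: %s", path), "drugrank_io_error")
  }
  for (nm in names(KB_SCHEMA)) {
    file <- file.path(path, paste0(nm, ".tsv"))
    con <- file(file, open = "w", encoding = "UTF-8")
    if (nm == "drugs") writeLines(paste0("# version=", kb$version), con)
    utils::write.table(kb[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    close(con)
  }
  invisible(path)
}

# Hand-written rows reproducing the two bundled clinical scenarios: a
# BRAF-mutant melanoma case (RAF/MEK inhibitors, MAP2K1 genetic dependency,
# CDKN2A deletion biomarker, MTOR repurposing candidates) and a
# PIK3CA-mutant breast case (alpelisib +/- fulvestrant, approved
# chemotherapies, DPYD pharmacogenetic rule).
curated_kb_tables <- function() {
  drugs <- data.frame(
    drug_id = c("D_VEMU", "D_TRAM", "D_EVER", "D_SIRO", "D_ALPE",
                "D_ALPE_FULV", "D_CAPE", "D_GEMC", "D_DOCE", "D_FU"),
    name = c("VEMURAFENIB", "TRAMETINIB", "EVEROLIMUS", "SIROLIMUS",
             "ALPELISIB", "ALPELISIB + FULVESTRANT", "CAPECITABINE",
             "GEMCITABINE", "DOCETAXEL", "FLUOROURACIL"),
    family = c("RAF inhibitor", "MEK inhibitor", "MTOR inhibitor",
               "MTOR inhibitor", "PI3K inhibitor",
               "PI3K inhibitor + ER antagonist", "Fluoropyrimidine",
               "Nucleoside analogue", "Taxane", "Fluoropyrimidine"),
    clinical_status = rep("APPROVED", 10),
    indications = c("SKIN", "SKIN", "BREAST,KIDNEY", "KIDNEY", "BREAST",
                    "BREAST", "BREAST,COLON", "BREAST,LUNG", "BREAST,PROSTATE",
                    "BREAST,COLON"),
    therapy_type = c("TARGETED", "TARGETED", "TARGETED", "TARGETED",
                     "TARGETED", "TARGETED", "CHEMOTHERAPY", "CHEMOTHERAPY",
                     "CHEMOTHERAPY", "CHEMOTHERAPY"),
    stringsAsFactors = FALSE
  )
  gene_annotations <- data.frame(
    gene = c("BRAF", "MAP2K1", "CDKN2A", "G6PD", "MTOR", "PIK3CA", "TP53",
             "DPYD", "MAPK3"),
    driver_role = c("ONCOGENE", "ONCOGENE", "TSG", "NONE", "ONCOGENE",
                    "ONCOGENE", "TSG", "NONE", "NONE"),
    essentiality = c(0.9, 0.8, 0.5, 0.3, 0.7, 0.85, 0.6, 0.1, 0.4),
    clinical_level = c("APPROVED_BIOMARKER", "APPROVED_BIOMARKER",
                       "LATE_TRIALS", "EARLY_TRIALS", "APPROVED_BIOMARKER",
                       "APPROVED_BIOMARKER", "LATE_TRIALS", "NONE", "NONE"),
    clinical_cancer_types = c("SKIN", "SKIN", "SKIN", "", "BREAST,KIDNEY",
                              "BREAST", "PAN_CANCER", "", ""),
    stringsAsFactors = FALSE
  )
  associations <- data.frame(
    drug_id = c("D_VEMU", "D_VEMU", "D_TRAM", "D_TRAM", "D_TRAM", "D_TRAM",
                "D_TRAM", "D_EVER", "D_SIRO", "D_ALPE", "D_ALPE_FULV",
                "D_CAPE", "D_GEMC", "D_DOCE", "D_FU"),
    gene = c("BRAF", "MAP2K1", "MAP2K1", "MAP2K1", "BRAF", "CDKN2A", "G6PD",
             "MTOR", "MTOR", "PIK3CA", "PIK3CA", "TP53", "TP53", "TP53",
             "TP53"),
    association_type = c("DIRECT_TARGET", "BIOMARKER", "DIRECT_TARGET",
                         "BIOMARKER", "BIOMARKER", "BIOMARKER", "BIOMARKER",
                         "DIRECT_TARGET", "DIRECT_TARGET", "DIRECT_TARGET",
                         "DIRECT_TARGET", "BIOMARKER", "BIOMARKER",
                         "BIOMARKER", "BIOMARKER"),
    response = rep("SENSITIVITY", 15),
    n_sources = c(5L, 3L, 5L, 2L, 4L, 2L, 1L, 4L, 3L, 5L, 3L, 3L, 3L, 3L, 2L),
    required_alteration = c("ONCOGENIC_SNV", "SNV", "ANY", "SNV",
                            "ONCOGENIC_SNV", "DEL", "ANY", "ONCOGENIC_SNV",
                            "ONCOGENIC_SNV", "ONCOGENIC_SNV", "ONCOGENIC_SNV",
                            "ANY", "ANY", "ANY", "ANY"),
    stringsAsFactors = FALSE
  )
  dependencies <- data.frame(
    context_gene = "BRAF", context_alteration = "ONCOGENIC_SNV",
    dependent_gene = "MAP2K1", stringsAsFactors = FALSE
  )
  pathway_edges <- data.frame(
    upstream_gene = c("BRAF", "MAP2K1"),
    downstream_gene = c("MAP2K1", "MAPK3"),
    stringsAsFactors = FALSE
  )
  pgx_rules <- data.frame(
    gene = "DPYD", variant_key = "1:97915614:C:T",
    function_effect = "DECREASED", zygosity_required = "HET",
    affected_drugs = "D_FU,D_CAPE", label = "MODERATELY_RECOMMENDED",
    stringsAsFactors = FALSE
  )
  list(drugs = drugs, associations = associations,
       gene_annotations = gene_annotations, dependencies = dependencies,
       pathway_edges = pathway_edges, pgx_rules = pgx_rules)
}

#' Generate a synthetic knowledge base
#'
#' Deterministic for a fixed seed. With `curated = TRUE` the output includes
#' the hand-written rows of the two bundled clinical scenarios (BRAF-mutant
#' melanoma; PIK3CA-mutant breast carcinoma with a DPYD pharmacogenetic
#' rule) on top of `n_genes` / `n_drugs` randomized filler rows.
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param n_genes,n_drugs Number of randomized genes / drugs (>= 0).
#' @param curated Include the curated scenario rows?
#' @return A validated [knowledge_base()].
#' @export
generate_fixture_kb <- function(seed = 1L, n_genes = 50L, n_drugs = 30L,
                                curated = FALSE) {
  if (n_genes < 0 || n_drugs < 0) {
    dr_abort("n_genes and n_drugs must be >= 0", "drugrank_argument_error")
  }
  withr::with_seed(seed, {
    genes <- if (n_genes > 0) sprintf("GENE%03d", seq_len(n_genes)) else character(0)
    drug_ids <- if (n_drugs > 0) sprintf("RD%03d", seq_len(n_drugs)) else character(0)
    codes <- setdiff(cancer_type_codes(), "PAN_CANCER")

    gene_annotations <- data.frame(
      gene = genes,
      driver_role = sample(DRIVER_ROLES, n_genes, replace = TRUE,
                           prob = c(0.3, 0.3, 0.05, 0.35)),
      essentiality = round(stats::runif(n_genes), 4),
      clinical_level = sample(CLINICAL_LEVELS, n_genes, replace = TRUE,
                              prob = c(0.15, 0.15, 0.2, 0.2, 0.3)),
      clinical_cancer_types = vapply(seq_len(max(n_genes, 0)), function(i) {
        k <- sample(0:2, 1)
        if (k == 0) return("")
        paste(sample(c(codes, "PAN_CANCER"), k), collapse = ",")
      }, character(1))[seq_len(n_genes)],
      stringsAsFactors = FALSE
    )
    drugs <- data.frame(
      drug_id = drug_ids,
      name = if (n_drugs > 0) sprintf("COMPOUND %03d", seq_len(n_drugs)) else character(0),
      family = sample(c("Kinase inhibitor", "Monoclonal antibody",
                        "Alkylating agent", "Antimetabolite", "Unknown"),
                      n_drugs, replace = TRUE),
      clinical_status = sample(CLINICAL_STATUS, n_drugs, replace = TRUE,
                               prob = c(0.4, 0.3, 0.3)),
      indications = vapply(seq_len(max(n_drugs, 0)), function(i) {
        k <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
        if (k == 0) return("")
        paste(sample(codes, k), collapse = ",")
      }, character(1))[seq_len(n_drugs)],
      therapy_type = sample(THERAPY_TYPES, n_drugs, replace = TRUE,
                            prob = c(0.5, 0.2, 0.1, 0.1, 0.1)),
      stringsAsFactors = FALSE
    )
    associations <- empty_kb_table("associations")
    if (n_drugs > 0 && n_genes > 0) {
      n_assoc <- 2L * n_drugs
      associations <- data.frame(
        drug_id = sample(drug_ids, n_assoc, replace = TRUE),
        gene = sample(genes, n_assoc, replace = TRUE),
        association_type = sample(ASSOCIATION_TYPES, n_assoc, replace = TRUE,
                                  prob = c(0.6, 0.4)),
        response = sample(RESPONSES, n_assoc, replace = TRUE,
                          prob = c(0.85, 0.15)),
        n_sources = sample(1:8, n_assoc, replace = TRUE),
        required_alteration = sample(ALTERATION_TOKENS, n_assoc,
                                     replace = TRUE,
                                     prob = c(0.2, 0.15, 0.1, 0.1, 0.05,
                                              0.05, 0.35)),
        stringsAsFactors = FALSE
      )
      associations <- associations[!duplicated(
        associations[, c("drug_id", "gene", "association_type", "response")]), ]
      rownames(associations) <- NULL
    }
    dependencies <- empty_kb_table("dependencies")
    if (n_genes >= 2) {
      n_dep <- max(1L, n_genes %/% 10L)
      ctx <- sample(genes, n_dep, replace = TRUE)
      dpd <- vapply(ctx, function(g) sample(setdiff(genes, g), 1), character(1))
      dependencies <- data.frame(
        context_gene = ctx,
        context_alteration = sample(c("SNV", "ONCOGENIC_SNV", "AMP", "DEL",
                                      "ANY"), n_dep, replace = TRUE),
        dependent_gene = dpd, stringsAsFactors = FALSE
      )
      rownames(dependencies) <- NULL
    }
    pathway_edges <- empty_kb_table("pathway_edges")
    if (n_genes >= 2) {
      n_edge <- max(1L, n_genes %/% 5L)
      up <- sample(genes, n_edge, replace = TRUE)
      down <- vapply(up, function(g) sample(setdiff(genes, g), 1), character(1))
      pathway_edges <- data.frame(upstream_gene = up, downstream_gene = down,
                                  stringsAsFactors = FALSE)
      pathway_edges <- pathway_edges[!duplicated(pathway_edges), ]
      rownames(pathway_edges) <- NULL
    }
    pgx_rules <- empty_kb_table("pgx_rules")
    if (n_genes >= 1 && n_drugs >= 1) {
      n_rule <- 2L
      pgx_rules <- data.frame(
        gene = sample(genes, n_rule, replace = TRUE),
        variant_key = sprintf("%d:%d:%s:%s",
                              sample(1:22, n_rule, replace = TRUE),
                              sample(1e5:2e6, n_rule),
                              sample(c("A", "C", "G", "T"), n_rule, TRUE),
                              sample(c("A", "C", "G", "T"), n_rule, TRUE)),
        function_effect = sample(c("NO_FUNCTION", "DECREASED"), n_rule,
                                 replace = TRUE),
        zygosity_required = sample(ZYGOSITIES, n_rule, replace = TRUE),
        affected_drugs = vapply(seq_len(n_rule), function(i)
          paste(sample(drug_ids, min(2, n_drugs)), collapse = ","),
          character(1)),
        label = sample(c("STRONGLY_NOT_RECOMMENDED", "MODERATELY_RECOMMENDED"),
                       n_rule, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }

    if (curated) {
      cur <- curated_kb_tables()
      drugs <- rbind(cur$drugs, drugs)
      gene_annotations <- rbind(cur$gene_annotations, gene_annotations)
      associations <- rbind(cur$associations, associations)
      dependencies <- rbind(cur$dependencies, dependencies)
      pathway_edges <- rbind(cur$pathway_edges, pathway_edges)
      pgx_rules <- rbind(cur$pgx_rules, pgx_rules)
    }
    knowledge_base(
      drugs = drugs, associations = associations,
      gene_annotations = gene_annotations, dependencies = dependencies,
      pathway_edges = pathway_edges, pgx_rules = pgx_rules,
      version = sprintf("synthetic-seed%d-g%d-d%d%s", seed, n_genes, n_drugs,
                        if (curated) "-curated" else "")
    )
  })
}
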