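# Shared fixtures: bundled curated knowledge base, patient input files,
# and in-code builders for small synthetic inputs.

curated_kb <- function() {
  load_knowledge_base(system.file("extdata", "kb_curated",
                                  package = "drugrank"))
}

patient_file <- function(name) {
  system.file("extdata", "patients", name, package = "drugrank")
}

melanoma_profile <- function(cancer_type = "SKIN", mode = "CLINICAL") {
  build_profile(
    somatic = parse_vcf(patient_file("melanoma.somatic.vcf"), "SOMATIC"),
    cnv = parse_cnv_tsv(patient_file("melanoma.cnv.tsv")),
    expr = parse_rnk(patient_file("melanoma.rnk")),
    cancer_type = cancer_type, mode = mode
  )
}

breast_profile <- function(cancer_type = "BREAST", mode = "CLINICAL") {
  build_profile(
    somatic = parse_vcf(patient_file("breast.somatic.vcf"), "SOMATIC"),
    germline = parse_vcf(patient_file("breast.germline.vcf"), "GERMLINE"),
    cancer_type = cancer_type, mode = mode
  )
}

write_temp_vcf <- function(body, samples = "SAMPLE") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##INFO=<ID=CONSEQUENCE,Number=1,Type=String,Description=\"term\">",
    "##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description=\"flag\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"population AF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

write_temp_lines <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# one-gene profile entry built directly (bypassing file parsing)
make_entry <- function(gene = "GENE1", consequences = character(0),
                       deleterious = TRUE, vaf = 0.4, popaf = NA_real_,
                       cnv = NA_character_, expr_class = "ABSENT",
                       assumed = FALSE) {
  somatic <- if (length(consequences)) {
    data.frame(chrom = "1", pos = seq_along(consequences), ref = "A",
               alt = "T", origin = "SOMATIC", genotype = "HET", vaf = vaf,
               gene = gene, consequence = consequences,
               predicted_deleterious = deleterious, population_af = popaf,
               stringsAsFactors = FALSE)
  } else {
    drugrank:::variant_columns()
  }
  list(gene = gene, somatic = somatic,
       germline = drugrank:::variant_columns(), cnv = cnv,
       expr_class = expr_class, expr_percentile = NA_real_,
       assumed = assumed)
}
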