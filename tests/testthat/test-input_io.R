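test_that("VCF parsing derives genotype and VAF from the first sample", {
  path <- write_temp_vcf(
    "7\t140453136\t.\tA\tT\t.\tPASS\tGENE=BRAF;CONSEQUENCE=missense;DELETERIOUS\tGT:AD\t0/1:60,40")
  rec <- parse_vcf(path, "SOMATIC")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$genotype, "HET")
  expect_equal(rec$vaf, 40 / (60 + 40))
  expect_equal(rec$gene, "BRAF")
  expect_true(rec$predicted_deleterious)
  expect_equal(rec$origin, "SOMATIC")
})

test_that("multiallelic sites split into one record per ALT allele", {
  path <- write_temp_vcf(
    "1\t1000\t.\tA\tT,G\t.\tPASS\tGENE=GENE1\tGT:AD\t1/2:10,30,60")
  rec <- parse_vcf(path, "SOMATIC")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$pos, c(1000L, 1000L))
  expect_equal(rec$alt, c("T", "G"))
  expect_equal(rec$genotype, c("HET", "HET"))
  expect_equal(rec$vaf, c(0.3, 0.6))
  hom <- parse_vcf(write_temp_vcf(
    "1\t2000\t.\tC\tT\t.\tPASS\tGENE=GENE2\tGT:AD\t1|1:0,50"), "GERMLINE")
  expect_equal(hom$genotype, "HOM")
})

test_that("VCF edge cases: empty body, headerless file, POPAF field", {
  empty <- write_temp_vcf(character(0))
  expect_equal(nrow(parse_vcf(empty, "SOMATIC")), 0)
  bad <- write_temp_lines(c("not", "a", "vcf"), ".vcf")
  expect_error(parse_vcf(bad, "SOMATIC"), class = "drugrank_format_error")
  withaf <- write_temp_vcf(
    "2\t500\t.\tG\tC\t.\tPASS\tGENE=GENE3;POPAF=0.001\tGT:AD\t0/1:5,5")
  expect_equal(parse_vcf(withaf, "SOMATIC")$population_af, 0.001)
})

test_that("CNV TSV parsing folds case, keeps last duplicate, rejects junk", {
  path <- write_temp_lines(c("gene_symbol\tstatus", "CDKN2A\tDEL",
                             "BRAF\tamp"), ".tsv")
  rec <- parse_cnv_tsv(path)
  expect_equal(rec$gene, c("CDKN2A", "BRAF"))
  expect_equal(rec$status, c("DEL", "AMP"))

  dup <- write_temp_lines(c("EGFR\tAMP", "EGFR\tDEL"), ".tsv")
  expect_warning(rec2 <- parse_cnv_tsv(dup), "EGFR")
  expect_equal(rec2$status, "DEL")

  header_only <- write_temp_lines("gene_symbol\tstatus", ".tsv")
  expect_equal(nrow(parse_cnv_tsv(header_only)), 0)

  junk <- write_temp_lines(c("A\tAMP", "B\tGAIN"), ".tsv")
  expect_error(parse_cnv_tsv(junk), "line 2",
               class = "drugrank_format_error")
})

test_that("RNK parsing keeps the most extreme duplicate and checks numbers", {
  path <- write_temp_lines(c("# comment", "G6PD\t3.4", "BRCA1\t-1.2"),
                           ".rnk")
  rec <- parse_rnk(path)
  expect_equal(rec$gene, c("G6PD", "BRCA1"))
  expect_equal(rec$rank_value, c(3.4, -1.2))

  dup <- write_temp_lines(c("X1\t2.0", "X1\t-5.0"), ".rnk")
  expect_warning(rec2 <- parse_rnk(dup), "X1")
  expect_equal(rec2$rank_value, -5.0)

  expect_error(parse_rnk(write_temp_lines("G\tNaNope", ".rnk")),
               class = "drugrank_format_error")
  expect_equal(nrow(parse_rnk(write_temp_lines(character(0), ".rnk"))), 0)
})

test_that("gene lists are uppercased, de-duplicated, order-preserving", {
  path <- write_temp_lines(c("MTOR", "braf", "BRAF", "", "tp53"), ".txt")
  expect_equal(parse_gene_list(path), c("MTOR", "BRAF", "TP53"))
  expect_equal(parse_gene_list(write_temp_lines(character(0), ".txt")),
               character(0))
})

test_that("build_profile merges channels per gene and classes expression", {
  somatic <- parse_vcf(patient_file("melanoma.somatic.vcf"), "SOMATIC")
  cnv <- parse_cnv_tsv(patient_file("melanoma.cnv.tsv"))
  expr <- parse_rnk(patient_file("melanoma.rnk"))
  prof <- build_profile(somatic = somatic, cnv = cnv, expr = expr,
                        cancer_type = "SKIN")
  cdkn2a <- prof$genes[["CDKN2A"]]
  expect_equal(cdkn2a$cnv, "DEL")
  expect_equal(cdkn2a$expr_class, "UNDER")
  expect_equal(prof$genes[["G6PD"]]$expr_class, "OVER")
  expect_equal(prof$genes[["FILLER09"]]$expr_class, "NEUTRAL")
  expect_equal(nrow(prof$genes[["BRAF"]]$somatic), 1)

  bare <- build_profile(genes = c("BRAF"), cancer_type = "ALL")
  expect_true(bare$genes[["BRAF"]]$assumed)
  expect_error(build_profile(), class = "drugrank_empty_query_error")
})

test_that("profiles are invariant to record order within a channel", {
  somatic <- parse_vcf(patient_file("melanoma.somatic.vcf"), "SOMATIC")
  expr <- parse_rnk(patient_file("melanoma.rnk"))
  p1 <- build_profile(somatic = somatic, expr = expr, cancer_type = "SKIN")
  p2 <- build_profile(somatic = somatic[rev(seq_len(nrow(somatic))), ],
                      expr = expr[sample(nrow(expr)), ],
                      cancer_type = "SKIN")
  expect_equal(names(p1$genes), names(p2$genes))
  expect_equal(p1$genes[["G6PD"]]$expr_class, p2$genes[["G6PD"]]$expr_class)
  expect_equal(p1$genes[["BRAF"]]$somatic, p2$genes[["BRAF"]]$somatic)
})
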