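test_that("containers validate their invariants", {
  d <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- toy_genotypes(d)
  expect_s3_class(g, "genotype_matrix")
  expect_equal(dim(g$dosage), c(3L, 2L))

  bad <- d; bad[2, 1] <- 3
  expect_error(toy_genotypes(bad), "invalid dosage value.*snp001")

  ann <- g$snps; ann$snp_id <- c("dup", "dup")
  expect_error(snp_annotation(ann), "duplicate")

  # methylation scale invariants and vocabularies
  cpgs <- toy_cpg_ann(2)
  v <- matrix(c(0.2, 0.5, 1.2, 0.1), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(methylation_matrix(v, cpgs, scale = "beta"), "\\[0, 1\\]")
  cpgs$island_relation <- c("OpenSea", "N_Shore")
  expect_silent(methylation_matrix(matrix(c(0.2, 0.5, 0.9, 0.1), 2,
                                          dimnames = list(c("a", "b"), NULL)),
                                   cpgs, scale = "beta"))
  cpgs$gene_region <- c("Body", "Enhancer")
  expect_error(cpg_annotation(cpgs), "unknown gene_region")

  expect_error(summary_stats_table(
    data.frame(snp_id = "rs1", effect_allele = "A", effect_sign = 2, p = 0.1)),
    "effect_sign")
  expect_error(phenotype_table(
    data.frame(sample_id = "a", age = 50, bmi = 25, cohort = "c1",
               not_a_trait = 1)), "unknown trait")
})

test_that("chromosome labels are normalized and validated", {
  expect_equal(methex:::normalize_chrom(c("chr1", "22", "chrX")),
               c("1", "22", "X"))
  expect_error(methex:::normalize_chrom("23"), "invalid chromosome")
})

test_that("genotype TSV round-trip is the identity and bad tokens error", {
  d <- matrix(c(0, 1, 2, NA, 0, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- toy_genotypes(d)
  tmp <- withr::local_tempdir()
  gp <- file.path(tmp, "g.tsv"); ap <- file.path(tmp, "a.tsv")
  write_genotypes(g, gp, ap)
  g2 <- suppressMessages(read_genotypes(gp, "dosage_tsv", ap))
  expect_identical(g2$dosage, g$dosage)
  expect_equal(g2$snps$maf, g$snps$maf, tolerance = 1e-12)
  expect_message(read_genotypes(gp, "dosage_tsv", ap), "1 missing")

  writeLines(c("sample_id\tsnpA\tsnpB", "s1\t0\t3", "s2\t1\t2"),
             file.path(tmp, "bad.tsv"))
  expect_error(read_genotypes(file.path(tmp, "bad.tsv"), "dosage_tsv", ap),
               "'3' at sample 's1', SNP 'snpB'")
})

test_that("plink text pair reads to the same dosages as the TSV route", {
  tmp <- withr::local_tempdir()
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), file.path(tmp, "t.map"))
  # rs1: minor allele G (3 of 8); rs2: minor allele T (2 of 8)
  writeLines(c("f1 s1 0 0 1 0 A G C C",
               "f2 s2 0 0 1 0 G G C T",
               "f3 s3 0 0 1 0 A A T C",
               "f4 s4 0 0 1 0 A A 0 0"),
             file.path(tmp, "t.ped"))
  g <- read_genotypes(file.path(tmp, "t.ped"), "plink_text",
                      file.path(tmp, "t.map"))
  expect_equal(unname(g$dosage[, "rs1"]), c(1, 2, 0, 0))
  expect_equal(unname(g$dosage[, "rs2"]), c(0, 1, 1, NA))
  expect_equal(g$snps$alt_allele, c("G", "T"))
})

test_that("typed matrix round-trips preserve values to 1e-12", {
  cpgs <- toy_cpg_ann(3)
  set.seed(4)
  m <- methylation_matrix(matrix(rnorm(12), 4,
                                 dimnames = list(sprintf("s%d", 1:4), NULL)),
                          cpgs, scale = "M")
  tmp <- withr::local_tempdir()
  write_methylation(m, file.path(tmp, "m.tsv"), file.path(tmp, "ma.tsv"))
  m2 <- read_matrix_tsv(file.path(tmp, "m.tsv"), "methylation",
                        file.path(tmp, "ma.tsv"))
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$cpgs, m$cpgs)

  ph <- phenotype_table(data.frame(
    sample_id = c("s1", "s2"), age = c(50, 60.5), bmi = c(24.2, 31.1),
    cohort = "c1", hba1c = c(5.5, NA), stringsAsFactors = FALSE))
  write_phenotypes(ph, file.path(tmp, "p.tsv"))
  # missing phenotype token is the empty string
  expect_true(grepl("\t$", readLines(file.path(tmp, "p.tsv"))[3]))
  ph2 <- read_matrix_tsv(file.path(tmp, "p.tsv"), "phenotype")
  expect_equal(ph2$hba1c, c(5.5, NA))
  expect_equal(ph2$age, c(50, 60.5))
})

test_that("write_results is header-stable and a byte-for-byte fixpoint", {
  tmp <- withr::local_tempdir()
  empty <- data.frame(snp_id = character(), p = numeric())
  write_results(empty, file.path(tmp, "e.tsv"))
  expect_identical(readLines(file.path(tmp, "e.tsv")), "snp_id\tp")

  rec <- data.frame(snp_id = c("rs1", "rs2"), feature_id = c("cg1", "cg2"),
                    beta = c(1 / 3, -2.5e-11), p = c(0.02, 3.1e-120),
                    stringsAsFactors = FALSE)
  f1 <- file.path(tmp, "r1.tsv"); f2 <- file.path(tmp, "r2.tsv")
  write_results(rec, f1)
  expect_length(readLines(f1), 3L)
  back <- read.table(f1, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$beta, rec$beta, tolerance = 0)  # %.17g round-trips exactly
  write_results(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
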