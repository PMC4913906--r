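make_pheno <- function(n = 120, seed = 61) {
  cfg <- simulation_config(n_samples = n, n_snps = 20, n_cpgs = 10,
                           n_transcripts = 0, seed = seed)
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)$methylation
  p <- simulate_phenotypes(g, m, cfg)
  list(g = g, p = p)
}

test_that("log transform hits exactly the registered traits", {
  ph <- phenotype_table(data.frame(
    sample_id = c("s1", "s2"), age = 50, bmi = 25, cohort = "c1",
    fasting_insulin = c(exp(1), 2), homa_ir = c(1, 4),
    cholesterol = c(4.5, 5.0), stringsAsFactors = FALSE))
  tr <- transform_traits(ph)
  expect_equal(tr$fasting_insulin, c(1, log(2)))
  expect_equal(tr$homa_ir, c(0, log(4)))
  expect_equal(tr$cholesterol, c(4.5, 5.0))  # untouched

  ph$homa_ir[2] <- -0.5
  expect_error(transform_traits(ph), "nonpositive homa_ir.*s2")
})

test_that("BMI enters the covariate set only for glycaemic traits", {
  co <- make_pheno()
  r1 <- assoc_phenotype(co$p, co$g, "snp00001", "hba1c")
  expect_match(r1$covariates_used, "bmi")
  r2 <- assoc_phenotype(co$p, co$g, "snp00001", "cholesterol")
  expect_false(grepl("bmi", r2$covariates_used))
  r3 <- assoc_phenotype(co$p, co$g, "snp00001", "whr")
  expect_false(grepl("bmi", r3$covariates_used))
  expect_error(assoc_phenotype(co$p, co$g, "snp00001", "height"),
               "not in registry")
})

test_that("phenotype association matches the normal-equations oracle", {
  co <- make_pheno(n = 90, seed = 8)
  rec <- assoc_phenotype(co$p, co$g, "snp00003", "ldl")
  C <- cbind(co$p$age,
             model.matrix(~factor(co$p$cohort))[, -1, drop = FALSE])
  o <- ols_oracle(co$p$ldl, co$g$dosage[, "snp00003"], C)
  expect_equal(rec$beta, unname(o$beta), tolerance = 1e-10)
  expect_equal(rec$se, unname(o$se), tolerance = 1e-10)
  expect_equal(rec$p, unname(o$p), tolerance = 1e-10)
})

test_that("replication needs internal and external p<0.05 plus sign match", {
  ann <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
                    pos = 1:4 * 1000, ref_allele = c("A", "A", "A", "A"),
                    alt_allele = c("G", "G", "G", "T"), maf = 0.2,
                    stringsAsFactors = FALSE)
  rec <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                    trait = "bmi", beta = c(0.5, 0.5, 0.5, -0.3),
                    p = c(0.03, 0.03, 0.03, 0.01), stringsAsFactors = FALSE)
  ext <- summary_stats_table(data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("G", "G", "A"),
    effect_sign = c(1, -1, -1),
    p = c(0.01, 0.01, 0.2), stringsAsFactors = FALSE))
  out <- replicate_filter(rec, ext, ann)
  expect_equal(out$replicated, c(TRUE, FALSE, FALSE, FALSE))
  # rs3: external reported on the other allele with sign -, harmonized to +
  expect_equal(out$external_sign[3], 1)
  expect_equal(out$status, c("found", "found", "found", "not_found"))
})

test_that("allele harmonization is an involution and order-invariant", {
  ann <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100, 200),
                    ref_allele = c("A", "C"), alt_allele = c("T", "G"),
                    maf = 0.3, stringsAsFactors = FALSE)
  rec <- data.frame(snp_id = c("rs1", "rs2"), trait = "whr",
                    beta = c(1, -1), p = c(0.01, 0.01),
                    stringsAsFactors = FALSE)
  ext <- summary_stats_table(data.frame(
    snp_id = c("rs2", "rs1"), effect_allele = c("C", "A"),
    effect_sign = c(1, 1), p = c(0.01, 0.01), stringsAsFactors = FALSE))
  out <- replicate_filter(rec, ext, ann)
  # flipping the reported allele twice restores the original record
  ext_flipped <- ext
  ext_flipped$effect_allele <- c("G", "T")
  ext_flipped$effect_sign <- -ext_flipped$effect_sign
  out2 <- replicate_filter(rec, ext_flipped, ann)
  expect_equal(out$external_sign, out2$external_sign)
  expect_equal(out$replicated, out2$replicated)
  # strand-ambiguous (A/T, C/G) SNPs are flagged but retained
  expect_true(all(out$strand_ambiguous))
  # row order of either table does not matter
  out3 <- replicate_filter(rec[2:1, ], ext, ann)
  expect_equal(out3$replicated, out$replicated[2:1])
})
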