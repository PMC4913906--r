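adjacent_r2 <- function(geno, block_size) {
  ann <- geno$snps
  out <- numeric(0)
  per <- split(seq_len(nrow(ann)), ann$chrom)
  for (idx in per) {
    for (j in seq_along(idx)[-1]) {
      # only within-block neighbours
      if (((j - 1) %% block_size) == 0) next
      out <- c(out, as.numeric(ld_r2(geno$dosage[, idx[j - 1]],
                                     geno$dosage[, idx[j]])))
    }
  }
  out
}

test_that("LD-block generator hits its correlation and MAF targets", {
  cfg <- simulation_config(n_samples = 1000, n_snps = 220, n_cpgs = 10,
                           n_transcripts = 0, ld_block_size = 5,
                           within_block_r = 0.95, seed = 11)
  g <- simulate_genotypes(cfg)
  r2 <- adjacent_r2(g, 5)
  expect_gt(mean(r2), 0.85)
  expect_lte(max(r2), 1.0)

  # independence limit
  cfg0 <- simulation_config(n_samples = 1000, n_snps = 220, n_cpgs = 10,
                            n_transcripts = 0, ld_block_size = 5,
                            within_block_r = 0, seed = 12)
  g0 <- simulate_genotypes(cfg0)
  expect_lt(mean(adjacent_r2(g0, 5)), 0.05)

  # realized MAF close to target; between-block LD negligible
  maf_hat <- colMeans(g$dosage) / 2
  maf_hat <- pmin(maf_hat, 1 - maf_hat)
  expect_lt(max(abs(maf_hat - g$snps$maf)), 0.05)
  between <- vapply(seq(5, 215, by = 5), function(j) {
    as.numeric(ld_r2(g$dosage[, j], g$dosage[, j + 1]))
  }, numeric(1))
  expect_lt(mean(between), 0.05)
})

test_that("the generator is deterministic given a seed", {
  cfg <- default_simulation_config(n_samples = 60, n_snps = 120,
                                   n_cpgs = 60, n_transcripts = 30,
                                   seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(as.data.frame(a$phenotypes), as.data.frame(b$phenotypes))
})

test_that("planted cis effects are recovered by a per-pair OLS oracle", {
  cfg <- simulation_config(
    n_samples = 200, n_snps = 60, n_cpgs = 30, n_transcripts = 20,
    seed = 5,
    planted_mqtls = data.frame(snp = 7, cpg = 4, beta = 1, relation = "cis"),
    planted_eqtls = data.frame(snp = 11, transcript = 6, beta = 1.5))
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)
  cv <- simulate_covariates(cfg)
  C <- as.matrix(cbind(cv$age, cv$bmi))
  o <- ols_oracle(m$methylation$values[, 4], g$dosage[, 7], C)
  expect_lt(o$p, 1e-10)
  expect_equal(unname(o$beta), 1, tolerance = 0.25)

  e <- simulate_expression(g, cfg)
  oe <- ols_oracle(e$values[, 6], g$dosage[, 11], C)
  expect_lt(oe$p, 1e-10)
})

test_that("intensity pairs are consistent with the emitted M-values", {
  cfg <- simulation_config(n_samples = 50, n_snps = 30, n_cpgs = 40,
                           n_transcripts = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)
  rec <- beta_to_m(m$intensities$meth, m$intensities$unmeth)
  keep <- m$methylation$values > -9  # rounding floor distorts extreme values
  expect_lt(max(abs(rec[keep] - m$methylation$values[keep])), 0.1)
})

test_that("CpG-SNP declarations co-locate the SNP and collide with mQTLs", {
  cfg <- simulation_config(n_samples = 50, n_snps = 30, n_cpgs = 40,
                           n_transcripts = 0, seed = 3,
                           planted_cpg_snps = data.frame(snp = 2, cpg = 5))
  g <- simulate_genotypes(cfg)
  hits <- detect_cpg_snps(g$snps, methex:::cpg_layout(cfg))
  expect_true(any(hits$snp_id == "snp00002" & hits$cpg_id == "cg0000005"))

  cfg_bad <- simulation_config(
    n_samples = 50, n_snps = 30, n_cpgs = 40, n_transcripts = 0, seed = 3,
    planted_cpg_snps = data.frame(snp = 2, cpg = 5),
    planted_mqtls = data.frame(snp = 2, cpg = 5, beta = 1, relation = "cis"))
  expect_error(simulate_methylation(g, cfg_bad), "collides")
})

test_that("mediation triples require their G->M arm and reactive rewrites", {
  cfg <- simulation_config(
    n_samples = 80, n_snps = 30, n_cpgs = 20, n_transcripts = 0, seed = 13,
    mediation_triples = data.frame(
      snp = 1, cpg = 1, trait = "hba1c", model = "causal",
      beta_gm = 1, beta_mp = 1, beta_gp = 0))
  expect_error(simulate_cohort(cfg), "without a planted G->M effect")

  cfg2 <- simulation_config(
    n_samples = 300, n_snps = 30, n_cpgs = 20, n_transcripts = 0, seed = 13,
    mediation_triples = data.frame(
      snp = 1, cpg = 1, trait = "whr", model = "reactive",
      beta_gm = 0, beta_mp = 0.9, beta_gp = 0.8))
  ch <- simulate_cohort(cfg2)
  # the reactive CpG must track the phenotype, not raw noise
  expect_gt(cor(ch$methylation$values[, 1], ch$phenotypes$whr)^2, 0.3)
})

test_that("unknown mediation model labels are rejected", {
  expect_error(simulation_config(
    n_samples = 50, n_snps = 10, n_cpgs = 10, n_transcripts = 0,
    mediation_triples = data.frame(
      snp = 1, cpg = 1, trait = "whr", model = "sideways",
      beta_gm = 1, beta_mp = 1, beta_gp = 1)), "unknown mediation model")
})
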