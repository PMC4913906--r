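test_that("cis/trans classification is boundary-inclusive and counts add up", {
  snp <- data.frame(snp_id = c("rs1", "rs2"), chrom = c("1", "2"),
                    pos = c(1000000, 1000000), stringsAsFactors = FALSE)
  cpg <- data.frame(cpg_id = c("cgA", "cgB", "cgC"), chrom = "1",
                    pos = c(1500000, 1500001, 999999),
                    stringsAsFactors = FALSE)
  res <- classify_pairs(snp, cpg, window = 500000)
  cis <- res$cis_pairs
  expect_true(any(cis$snp_id == "rs1" & cis$feature_id == "cgA"))   # 500000
  expect_false(any(cis$snp_id == "rs1" & cis$feature_id == "cgB"))  # 500001
  expect_true(any(cis$snp_id == "rs1" & cis$feature_id == "cgC"))
  expect_false(any(cis$snp_id == "rs2"))  # different chromosome
  expect_equal(res$classification$n_total_pairs, 6)
  expect_equal(res$classification$n_cis_pairs +
                 res$classification$n_trans_pairs, 6)
  expect_equal(cis$distance[cis$feature_id == "cgA"], 500000)

  expect_error(classify_pairs(snp, data.frame(cpg_id = "x", chrom = NA,
                                              pos = 1)),
               "unannotated")
})

test_that("per-pair regression matches a normal-equations oracle", {
  # perfect fit: response equals dosage
  g <- c(0, 1, 2, 0, 1, 2, 1, 0)
  f <- fit_qtl(g, g)
  expect_equal(f$beta, 1, tolerance = 1e-12)
  expect_lt(f$p, 1e-12)

  # constructed orthogonal response
  gc <- g - mean(g)
  y <- rnorm(8)
  y <- y - mean(y) - sum(y * gc) / sum(gc^2) * gc
  expect_lt(abs(fit_qtl(y, g)$beta), 1e-10)

  # 6-sample fixture with one covariate vs the oracle
  set.seed(31)
  g6 <- c(0, 1, 2, 2, 1, 0)
  cov1 <- c(3.2, 1.1, 5.5, 2.0, 4.4, 0.7)
  y6 <- 0.6 * g6 + 0.2 * cov1 + rnorm(6, 0, 0.3)
  f6 <- fit_qtl(y6, g6, data.frame(cov1 = cov1))
  o6 <- ols_oracle(y6, g6, cbind(cov1))
  expect_equal(f6$beta, unname(o6$beta), tolerance = 1e-10)
  expect_equal(f6$se, unname(o6$se), tolerance = 1e-10)
  expect_equal(f6$p, unname(o6$p), tolerance = 1e-10)

  # zero-variance dosage is flagged, not fatal
  expect_equal(fit_qtl(rnorm(10), rep(1, 10))$flag, "zero_variance")
})

make_scan_cohort <- function(n = 120, n_snps = 20, n_cpgs = 20, seed = 77) {
  cfg <- simulation_config(n_samples = n, n_snps = n_snps, n_cpgs = n_cpgs,
                           n_transcripts = 0, seed = seed)
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)$methylation
  cv <- simulate_covariates(cfg)
  list(g = g, m = m,
       C = cv[, c("age", "bmi", "cohort")])
}

test_that("matrix scan equals per-pair OLS for any covariate set", {
  co <- make_scan_cohort()
  # inject some missing dosages to exercise mean imputation
  d <- co$g$dosage; d[cbind(c(3, 50, 99), c(1, 7, 13))] <- NA
  g <- genotype_matrix(d, co$g$snps)
  rec <- scan_pairs(g$dosage, co$m$values, co$C)
  Cm <- cbind(co$C$age, co$C$bmi,
              model.matrix(~factor(co$C$cohort))[, -1, drop = FALSE])
  dmax <- 0
  for (i in seq_len(nrow(rec))) {
    gg <- g$dosage[, rec$snp_id[i]]
    gg[is.na(gg)] <- mean(gg, na.rm = TRUE)
    o <- ols_oracle(co$m$values[, rec$feature_id[i]], gg, Cm)
    dmax <- max(dmax, abs(rec$t_stat[i] - o$t_stat),
                abs(rec$beta[i] - o$beta))
  }
  expect_lt(dmax, 1e-8)

  # chunked cross scan agrees with the pairwise formulation
  cross <- methex:::scan_cross(g$dosage, co$m$values, co$C, chunk = 7L)
  key <- paste(rec$snp_id, rec$feature_id)
  cross <- cross[match(key, paste(cross$snp_id, cross$feature_id)), ]
  expect_equal(cross$t_stat, rec$t_stat, tolerance = 1e-10)
})

test_that("statistics are invariant to a joint permutation of samples", {
  co <- make_scan_cohort(n = 80, n_snps = 10, n_cpgs = 10, seed = 5)
  rec1 <- scan_pairs(co$g$dosage, co$m$values, co$C)
  set.seed(2); perm <- sample(80)
  rec2 <- scan_pairs(co$g$dosage[perm, ], co$m$values[perm, ],
                     co$C[perm, ])
  expect_equal(rec1$t_stat, rec2$t_stat, tolerance = 1e-10)
  expect_equal(rec1$p, rec2$p, tolerance = 1e-10)
})

test_that("scan_qtl separates cis and trans and keeps the planted minimum", {
  cfg <- simulation_config(
    n_samples = 200, n_snps = 60, n_cpgs = 40, n_transcripts = 0, seed = 19,
    # snp 8 and cpg 5 share chromosome 3 under the deterministic layout
    planted_mqtls = data.frame(snp = 8, cpg = 5, beta = 1, relation = "cis"))
  g <- simulate_genotypes(cfg)
  m <- simulate_methylation(g, cfg)$methylation
  cv <- simulate_covariates(cfg)
  C <- cv[, c("age", "bmi", "cohort")]
  cis <- scan_qtl(g, m, C, "cis")
  trans <- scan_qtl(g, m, C, "trans")
  expect_equal(nrow(cis) + nrow(trans), 60 * 40)
  expect_true(all(cis$distance <= 500000, na.rm = TRUE))
  expect_true(all(is.na(trans$distance)))
  top <- cis[which.min(cis$p), ]
  expect_equal(top$snp_id, "snp00008")
  expect_equal(top$feature_id, "cg0000005")
})

test_that("CpG-SNP detection keeps distances 0 and 1 only", {
  snp <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = "3",
                    pos = c(100, 201, 305, 500), stringsAsFactors = FALSE)
  cpg <- data.frame(cpg_id = c("x", "y", "z"), chrom = "3",
                    pos = c(100, 200, 303), stringsAsFactors = FALSE)
  hits <- detect_cpg_snps(snp, cpg)
  expect_setequal(paste(hits$snp_id, hits$cpg_id), c("a x", "b y"))
  expect_setequal(hits$distance, c(0, 1))
})

test_that("methylation-expression scan respects the asymmetric window", {
  # gene span [1,000,000; 1,005,000]
  tx <- data.frame(transcript_id = "t1", chrom = "1", start = 1000000,
                   end = 1005000, gene = "G1", stringsAsFactors = FALSE)
  cpg <- data.frame(
    cpg_id = c("up_ok", "up_far", "down_ok", "down_far"),
    chrom = "1",
    pos = c(1000000 - 400000,   # 400 kb upstream: tested
            1000000 - 600000,   # beyond 500 kb upstream: not tested
            1005000 + 90000,    # 90 kb downstream: tested
            1005000 + 200000),  # 200 kb downstream: not tested
    gene = "", gene_region = "Body", island_relation = "OpenSea",
    stringsAsFactors = FALSE)
  set.seed(55)
  n <- 60
  mv <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("s%d", 1:n), NULL))
  ev <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%d", 1:n), NULL))
  ev[, 1] <- ev[, 1] + 0.8 * mv[, 1]
  meth <- methylation_matrix(mv, cpg, scale = "M")
  expr <- expression_matrix(ev, tx)
  rec <- scan_methylation_expression(meth, expr)
  expect_setequal(rec$cpg_id, c("up_ok", "down_ok"))
  # BH q-values equal the step-up formula applied to the scan's p-values
  p <- rec$p[order(rec$p)]
  m <- length(p)
  q_hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(sort(rec$q), q_hand, tolerance = 1e-12)
})

test_that("BH attachment reproduces the worked three-p example", {
  p <- c(0.001, 0.02, 0.9)
  m <- length(p)
  q_hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(q_hand, c(0.003, 0.03, 0.9), tolerance = 1e-12)
  expect_equal(p.adjust(p, "BH"), q_hand, tolerance = 1e-12)
})
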