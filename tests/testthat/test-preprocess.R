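test_that("HWE chi-squared matches its closed form", {
  expect_equal(hwe_test(25, 50, 25), 1.0)
  # (50,0,50): expected (25,50,25), chi2 = 100
  expect_equal(hwe_test(50, 0, 50),
               pchisq(100, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(hwe_test(0, 0, 10), 1.0)  # monomorphic convention
  expect_error(hwe_test(0, 0, 0), "> 0")
})

test_that("SNP filter applies missingness, HWE and MAF rules in order", {
  # 100 samples; build 10 SNPs, 3 violating exactly one rule each
  set.seed(42)
  n <- 100
  good <- function() rbinom(n, 2, 0.3)
  d <- cbind(
    s1 = good(), s2 = good(), s3 = good(), s4 = good(), s5 = good(),
    s6 = good(), s7 = good(),
    miss = {x <- good(); x[1:6] <- NA; x},           # 6% missing > 5%
    hwe = rep(c(0, 2), each = n / 2),                # no hets at p = 0.5
    rare = c(1, rep(0, n - 1)))                      # maf 0.005 < 0.05
  rownames(d) <- sprintf("i%03d", 1:n)
  g <- toy_genotypes(d)
  res <- filter_snps(g)
  expect_equal(res$report$n_output, 7L)
  expect_equal(unname(res$report$n_removed_by_rule),
               c(1L, 1L, 1L))
  expect_setequal(res$genotypes$snps$snp_id,
                  g$snps$snp_id[1:7])
  # report reconciles exactly
  expect_equal(res$report$n_input - sum(res$report$n_removed_by_rule),
               res$report$n_output)
})

test_that("MAF exactly at the threshold is retained (strict < rule)", {
  # 100 samples, 10 minor alleles -> maf 0.05 exactly
  d <- cbind(boundary = c(rep(1, 10), rep(0, 90)),
             filler = rbinom(100, 2, 0.4))
  rownames(d) <- sprintf("i%03d", 1:100)
  res <- filter_snps(toy_genotypes(d), hwe_alpha = 1e-12)
  expect_true("boundary" %in% res$genotypes$snps$snp_id)
})

test_that("probe filter drops detection failures, non-CpG and SNP probes", {
  ids <- c("cg01", "cg02", "ch.1.123", "rs123", "cg05")
  ann <- toy_cpg_ann(5); ann$cpg_id <- ids
  vals <- matrix(rnorm(20), 4, 5, dimnames = list(sprintf("s%d", 1:4), ids))
  meth <- methylation_matrix(vals, ann, scale = "M")
  detp <- matrix(0.001, 4, 5); detp[, 2] <- 0.02
  res <- filter_probes(meth, detp)
  expect_setequal(res$methylation$cpgs$cpg_id, c("cg01", "cg05"))
  expect_equal(unname(res$report$n_removed_by_rule), c(1L, 1L, 1L))

  # all-clean fixture passes untouched; missing detection table errors
  clean <- methylation_matrix(vals[, c(1, 2, 5)],
                              ann[c(1, 2, 5), ], scale = "M")
  expect_equal(filter_probes(clean, detp[, c(1, 2, 5)] * 0)$report$n_output, 3L)
  expect_error(filter_probes(meth, NULL, max_mean_detp = 0.01),
               "detection_p is required")
})

test_that("intensity to M transform is exact on powers of two and guarded", {
  expect_equal(beta_to_m(255, 63), 2.0)
  expect_equal(beta_to_m(100, 100), 0.0)
  expect_equal(beta_to_m(-10, 0), 0.0)
  # monotone increasing in meth for fixed unmeth
  x <- seq(-5, 5000, length.out = 200)
  expect_true(all(diff(beta_to_m(x, 700)) >= 0))
})

test_that("quantile normalization equalizes columns and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  set.seed(8)
  x <- matrix(rexp(300), 60, 5)
  q1 <- quantile_normalize(x)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  expect_equal(max(abs(colMeans(q1) - mean(colMeans(q1)))), 0, tolerance = 1e-12)
  # within-column ranks preserved
  expect_equal(order(q1[, 3]), order(x[, 3]))
  # ties share the averaged target value
  xt <- cbind(c(1, 1, 5), c(2, 4, 9))
  qt <- quantile_normalize(xt)
  expect_equal(qt[1, 1], qt[2, 1])
  expect_equal(qt[1, 1], mean(rowMeans(apply(xt, 2, sort))[1:2]))
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "complete")
})

test_that("batch adjustment matches pooled moments per feature", {
  set.seed(9)
  x <- matrix(rnorm(200), 40, 5)
  batch <- rep(c("b1", "b2"), each = 20)
  x[batch == "b2", ] <- x[batch == "b2", ] + 10   # known shift
  adj <- adjust_batch(x, batch)
  for (b in c("b1", "b2")) {
    expect_equal(colMeans(adj[batch == b, ]), colMeans(x),
                 tolerance = 1e-10)
    expect_equal(apply(adj[batch == b, ], 2, sd), apply(x, 2, sd),
                 tolerance = 1e-10)
  }
  # single batch is the identity
  expect_equal(adjust_batch(x, rep("b1", 40)), x, tolerance = 1e-12)
  expect_error(adjust_batch(x, c("solo", rep("b1", 39))), "single-sample")
})
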