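# independent brute-force oracles: full r² matrix from first principles and
# a literal greedy re-walk, kept free of the package's pruning code
brute_r2 <- function(d) {
  n <- ncol(d)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- d[, i]; b <- d[, j]
    ok <- !is.na(a) & !is.na(b)
    va <- var(a[ok]); vb <- var(b[ok])
    out[i, j] <- if (is.na(va) || is.na(vb) || va == 0 || vb == 0) 0 else
      cor(a[ok], b[ok])^2
  }
  diag(out) <- 1
  out
}

brute_greedy <- function(pos, r2, threshold, window) {
  tags <- integer(0)
  for (i in seq_along(pos)) {
    near <- tags[abs(pos[tags] - pos[i]) <= window]
    if (!length(near) || max(r2[i, near]) < threshold) tags <- c(tags, i)
  }
  tags
}

test_that("dosage r² matches hand-computed Pearson values", {
  expect_equal(as.numeric(ld_r2(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2))), 1)
  expect_equal(as.numeric(ld_r2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0))), 1)
  expect_equal(as.numeric(ld_r2(c(0, 1, 2, 0), c(0, 0, 2, 2))), 1 / 11,
               tolerance = 1e-12)
  flagged <- ld_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))
  expect_equal(as.numeric(flagged), 0)
  expect_true(attr(flagged, "undefined"))
})

test_that("greedy tagging collapses LD clusters and keeps independents", {
  # two perfectly correlated adjacent SNPs -> one tag
  g <- c(0, 1, 2, 0, 1, 2, 1, 1)
  d <- cbind(a = g, b = g)
  rownames(d) <- sprintf("s%d", 1:8)
  expect_length(tag_prune(toy_genotypes(d)), 1L)

  # mutually (near) independent SNPs are all tags
  set.seed(12)
  d2 <- sapply(1:6, function(i) rbinom(400, 2, 0.4))
  colnames(d2) <- NULL; rownames(d2) <- sprintf("s%03d", 1:400)
  expect_length(tag_prune(toy_genotypes(d2)), 6L)
})

test_that("tag sets equal a brute-force greedy recount and are idempotent", {
  cfg <- simulation_config(n_samples = 300, n_snps = 88, n_cpgs = 5,
                           n_transcripts = 0, ld_block_size = 4,
                           within_block_r = 0.9, seed = 41)
  g <- simulate_genotypes(cfg)
  tags <- tag_prune(g, 0.9, 500000)
  # brute-force recount per chromosome in annotation order
  expected <- character(0)
  for (ch in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ch)
    idx <- idx[order(g$snps$pos[idx], g$snps$snp_id[idx])]
    keep <- brute_greedy(g$snps$pos[idx],
                         brute_r2(g$dosage[, idx, drop = FALSE]),
                         0.9, 500000)
    expected <- c(expected, g$snps$snp_id[idx][keep])
  }
  expect_setequal(tags, expected)

  # idempotence: pruning the tag set returns it unchanged
  sub <- genotype_matrix(g$dosage[, tags, drop = FALSE],
                         g$snps[match(tags, g$snps$snp_id), ])
  expect_setequal(tag_prune(sub, 0.9, 500000), tags)

  # raising the r² threshold never decreases the number of tags
  n_tags <- vapply(c(0.2, 0.5, 0.8, 0.95, 1 - 1e-9),
                   function(th) length(tag_prune(g, th, 500000)), numeric(1))
  expect_true(all(diff(n_tags) >= 0))
})

test_that("cis correction value sums per-CpG tag counts", {
  # 1 CpG with 3 mutually independent cis SNPs -> 3
  set.seed(3)
  d <- sapply(1:3, function(i) rbinom(500, 2, 0.3))
  rownames(d) <- sprintf("s%03d", 1:500)
  g <- toy_genotypes(d)
  cpg1 <- toy_cpg_ann(1)
  expect_equal(cis_correction_value(g, cpg1)$value, 3)

  # 2 CpGs sharing one fully collapsed SNP cluster -> counted per CpG
  g2 <- c(0, 2, 1, 0, 2, 1, 1, 0)
  d2 <- cbind(a = g2, b = g2, c = g2); rownames(d2) <- sprintf("s%d", 1:8)
  gm <- toy_genotypes(d2)
  expect_equal(cis_correction_value(gm, toy_cpg_ann(2))$value, 2)
})

test_that("correction plan equals brute-force recounts on a synthetic cohort", {
  cfg <- simulation_config(n_samples = 150, n_snps = 440, n_cpgs = 110,
                           n_transcripts = 0, ld_block_size = 4,
                           within_block_r = 0.85, seed = 23)
  g <- simulate_genotypes(cfg)
  cpgs <- methex:::cpg_layout(cfg)
  plan <- correction_plan(g, cpgs)

  # brute-force per-CpG recount
  cis_expected <- 0
  for (k in seq_len(nrow(cpgs))) {
    idx <- which(g$snps$chrom == cpgs$chrom[k] &
                   abs(g$snps$pos - cpgs$pos[k]) <= 500000)
    if (!length(idx)) next
    idx <- idx[order(g$snps$pos[idx], g$snps$snp_id[idx])]
    keep <- brute_greedy(g$snps$pos[idx],
                         brute_r2(g$dosage[, idx, drop = FALSE]),
                         0.9, 500000)
    cis_expected <- cis_expected + length(keep)
  }
  expect_equal(plan$cis_correction_value, cis_expected)
  expect_equal(plan$trans_correction_value,
               nrow(cpgs) * plan$n_tags_global - cis_expected)
  expect_equal(plan$cis_threshold, 0.05 / cis_expected)
})

test_that("trans correction arithmetic and thresholds match closed forms", {
  expect_equal(trans_correction_value(10, 5, 8), 42)
  expect_equal(trans_correction_value(1, 1, 0), 1)
  expect_error(trans_correction_value(1, 1, 1), "positive")
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 104023091), 2), 4.8e-10)
})

test_that("eQTL correction values cover both modes", {
  set.seed(6)
  d <- sapply(1:2, function(i) rbinom(400, 2, 0.35))
  rownames(d) <- sprintf("s%03d", 1:400)
  g <- toy_genotypes(d)
  tx1 <- data.frame(transcript_id = "t1", chrom = "1", start = 500,
                    end = 2500, gene = "G", stringsAsFactors = FALSE)
  # 1 transcript, 2 independent cis SNPs -> 2
  expect_equal(eqtl_correction_values(g, tx1, "cis"), 2)
  # trans mode: pruned count x transcripts
  tx4 <- tx1[rep(1, 4), ]; tx4$transcript_id <- paste0("t", 1:4)
  expect_equal(eqtl_correction_values(g, tx4, "trans"), 8)
  expect_error(eqtl_correction_values(
    genotype_matrix(d[, 0, drop = FALSE], g$snps[0, ]), tx1, "cis"),
    "empty")
})
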