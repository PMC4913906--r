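# Small programmatic fixtures shared across test files.

# genotype container from a plain dosage matrix, with evenly spaced
# positions on one chromosome unless an annotation is supplied
toy_genotypes <- function(dosage, chrom = "1", spacing = 1000, ann = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  if (is.null(ann)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("snp%03d", seq_len(ncol(dosage)))
    ann <- data.frame(
      snp_id = ids,
      chrom = chrom,
      pos = 1000 + spacing * (seq_len(ncol(dosage)) - 1),
      ref_allele = "A", alt_allele = "G",
      maf = pmax(pmin(colMeans(dosage, na.rm = TRUE) / 2, 0.5), 0.01),
      stringsAsFactors = FALSE)
  }
  genotype_matrix(dosage, ann)
}

toy_cpg_ann <- function(n, chrom = "1", start = 1500, spacing = 1000) {
  data.frame(cpg_id = sprintf("cg%03d", seq_len(n)), chrom = chrom,
             pos = start + spacing * (seq_len(n) - 1), gene = "",
             gene_region = "Body", island_relation = "OpenSea",
             stringsAsFactors = FALSE)
}

# independent per-pair OLS oracle via explicit normal equations (kept free
# of the package's fitting code on purpose)
ols_oracle <- function(y, g, C = NULL) {
  X <- cbind(1, g, C)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% b
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * solve(XtX)[2, 2])
  t_stat <- b[2] / se
  list(beta = b[2], se = se, t_stat = t_stat,
       p = 2 * pt(-abs(t_stat), df))
}
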