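# Genotype and methylation QC and normalization.
#
# Filter rules follow the array-era defaults: SNPs are removed on
# missingness > 5%, Hardy-Weinberg p < 0.001, or MAF < 0.05 (strict
# inequalities, rules applied in that order with first-rule-wins
# bookkeeping); probes on mean detection p > 0.01, non-CpG ("ch."-prefixed)
# ids, and SNP-probe ("rs"-prefixed) ids.

qc_report <- function(n_input, removed, n_output, params) {
  stopifnot(n_input - sum(removed) == n_output)
  structure(list(n_input = n_input, n_removed_by_rule = removed,
                 n_output = n_output, params = params),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$n_input, "->", x$n_output, "\n")
  for (r in names(x$n_removed_by_rule)) {
    cat("  removed by", r, ":", x$n_removed_by_rule[[r]], "\n")
  }
  invisible(x)
}

#' Convert a QC report to a writable data.frame
#' @param report a `qc_report`.
#' @return data.frame with one row per rule plus input/output totals.
#' @export
qc_report_table <- function(report) {
  data.frame(rule = c("input", names(report$n_removed_by_rule), "output"),
             n = c(report$n_input, unname(unlist(report$n_removed_by_rule)),
                   report$n_output),
             stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Plain 1-df Pearson chi-squared goodness of fit of the observed genotype
#' counts against expected counts from the observed allele frequency (no
#' continuity correction, no exact test). A monomorphic marker (one allele
#' absent) returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa nonnegative integer genotype counts, total > 0.
#' @return p-value in \[0, 1\].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be > 0")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Filter SNPs on missingness, HWE and MAF
#'
#' Rules are applied in a fixed order (missingness, then HWE, then MAF) and a
#' SNP removed by an earlier rule is not counted again, so the QC report
#' totals reconcile exactly. MAF is recomputed from non-missing dosages.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing remove if missing fraction > this (default 0.05).
#' @param hwe_alpha remove if HWE p < this (default 0.001).
#' @param min_maf remove if recomputed MAF < this, strict (default 0.05).
#' @return list with `genotypes` (filtered, MAF updated) and `report`
#'   (a `qc_report`).
#' @export
filter_snps <- function(geno, max_missing = 0.05, hwe_alpha = 0.001,
                        min_maf = 0.05) {
  d <- geno$dosage
  miss_frac <- colMeans(is.na(d))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 2, na.rm = TRUE))
  }, numeric(1))
  maf <- dosage_maf(d)
  fail_miss <- miss_frac > max_missing
  fail_hwe <- !fail_miss & hwe_p < hwe_alpha
  fail_maf <- !fail_miss & !fail_hwe & (is.na(maf) | maf < min_maf)
  keep <- !(fail_miss | fail_hwe | fail_maf)
  if (!any(keep)) stop("all SNPs removed by QC; review filter parameters")
  report <- qc_report(
    n_input = ncol(d),
    removed = c(missingness = sum(fail_miss), hwe = sum(fail_hwe),
                maf = sum(fail_maf)),
    n_output = sum(keep),
    params = list(max_missing = max_missing, hwe_alpha = hwe_alpha,
                  min_maf = min_maf))
  ann <- geno$snps[keep, , drop = FALSE]
  ann$maf <- maf[keep]
  list(genotypes = genotype_matrix(d[, keep, drop = FALSE], ann),
       report = report)
}

#' Filter samples on genotype call rate
#'
#' Optional sample-level pre-filter: samples with a call rate below
#' `min_call_rate` are removed.
#'
#' @param geno a [genotype_matrix()].
#' @param min_call_rate retain samples with call rate >= this (default 0.98).
#' @return list with `genotypes` and `report`.
#' @export
filter_samples <- function(geno, min_call_rate = 0.98) {
  call_rate <- rowMeans(!is.na(geno$dosage))
  keep <- call_rate >= min_call_rate
  if (!any(keep)) stop("all samples removed by call-rate filter")
  report <- qc_report(nrow(geno$dosage),
                      c(call_rate = sum(!keep)), sum(keep),
                      list(min_call_rate = min_call_rate))
  list(genotypes = genotype_matrix(geno$dosage[keep, , drop = FALSE],
                                   geno$snps),
       report = report)
}

#' Filter methylation probes
#'
#' Removes probes with mean detection p-value above `max_mean_detp`, non-CpG
#' probes ("ch."-prefixed ids) and SNP probes ("rs"-prefixed ids), in that
#' order with first-rule-wins counting.
#'
#' @param meth a [methylation_matrix()].
#' @param detection_p matrix of per-call detection p-values aligned to
#'   `meth$values`; required when `max_mean_detp` is not `NULL`.
#' @param max_mean_detp remove if mean detection p > this (default 0.01);
#'   `NULL` disables the rule.
#' @param drop_non_cpg,drop_snp_probes toggle the id-prefix rules.
#' @return list with `methylation` and `report`.
#' @export
filter_probes <- function(meth, detection_p = NULL, max_mean_detp = 0.01,
                          drop_non_cpg = TRUE, drop_snp_probes = TRUE) {
  ids <- meth$cpgs$cpg_id
  n <- length(ids)
  if (!is.null(max_mean_detp)) {
    if (is.null(detection_p)) {
      stop("detection_p is required when max_mean_detp is set")
    }
    if (!all(dim(detection_p) == dim(meth$values))) {
      stop("detection_p dimensions do not match the methylation matrix")
    }
    fail_detp <- colMeans(detection_p) > max_mean_detp
  } else {
    fail_detp <- rep(FALSE, n)
  }
  fail_ch <- !fail_detp & drop_non_cpg & startsWith(ids, "ch.")
  fail_rs <- !fail_detp & !fail_ch & drop_snp_probes & startsWith(ids, "rs")
  keep <- !(fail_detp | fail_ch | fail_rs)
  if (!any(keep)) stop("all probes removed by QC")
  report <- qc_report(n,
                      c(detection_p = sum(fail_detp),
                        non_cpg = sum(fail_ch),
                        snp_probe = sum(fail_rs)),
                      sum(keep),
                      list(max_mean_detp = max_mean_detp,
                           drop_non_cpg = drop_non_cpg,
                           drop_snp_probes = drop_snp_probes))
  list(methylation = methylation_matrix(meth$values[, keep, drop = FALSE],
                                        meth$cpgs[keep, , drop = FALSE],
                                        scale = meth$scale),
       report = report)
}

#' Intensity pair to M-value transform
#'
#' `M = log2((max(meth, 0) + 1) / (max(unmeth, 0) + 1))`: the log2 ratio of
#' methylated to unmethylated channel intensity, with floor-at-zero-plus-one
#' guards so the transform is total even for background-subtracted (negative)
#' intensities. Elementwise over matrices.
#'
#' @param meth_intensity,unmeth_intensity finite intensities (scalars,
#'   vectors or matrices of matching shape).
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(meth_intensity, unmeth_intensity) {
  log2((pmax(meth_intensity, 0) + 1) / (pmax(unmeth_intensity, 0) + 1))
}

#' Quantile normalization
#'
#' Forces every column of `x` onto the identical empirical distribution equal
#' to the across-column mean of order statistics, preserving within-column
#' ranks. Ties within a column receive the average of the target values over
#' the tied ranks. Idempotent.
#'
#' @param x numeric matrix with no missing values; columns are the units
#'   being equalized (for a samples x features methylation matrix, pass the
#'   transpose to normalize across samples).
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("quantile_normalize requires a complete matrix")
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    y <- numeric(nrow(x))
    y[order(x[, j])] <- target
    out[, j] <- stats::ave(y, x[, j], FUN = mean)
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Location-scale batch adjustment
#'
#' Per feature (column), each batch is shifted and scaled so batch means
#' equal the pooled mean and batch SDs equal the pooled SD. A batch with zero
#' within-batch SD for a feature is shifted only.
#'
#' @param x numeric matrix, samples in rows and features in columns.
#' @param batch batch label per sample (>= 2 samples per batch).
#' @return The adjusted matrix.
#' @export
adjust_batch <- function(x, batch) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  if (length(batch) != nrow(x)) stop("one batch label per sample required")
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("single-sample batch(es): ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  out <- x
  pooled_mean <- colMeans(x)
  pooled_sd <- apply(x, 2, stats::sd)
  for (b in names(tab)) {
    rows <- batch == b
    bm <- colMeans(x[rows, , drop = FALSE])
    bs <- apply(x[rows, , drop = FALSE], 2, stats::sd)
    scale <- ifelse(bs > 0, pooled_sd / bs, 1)
    out[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, bm, "-"),
                         2, scale, "*")
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, pooled_mean, "+")
  }
  out
}
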