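# LD-aware modified Bonferroni machinery: pairwise r², greedy tag pruning,
# per-CpG tag counting, and the cis/trans correction values and thresholds.
#
# The number of "independent" tests is counted by pairwise tagging at
# r² < 0.9: a SNP is represented by an already-chosen tag when their dosage
# r² reaches the threshold, and the Bonferroni denominator is the tag count
# (summed per CpG in cis; CpGs x global tags minus the cis value in trans).

#' Pairwise LD as squared dosage correlation
#'
#' Composite LD on unphased data: the squared Pearson correlation of the two
#' dosage vectors, computed on pairwise-complete observations. If either
#' vector has zero variance the value is undefined; 0 is returned with
#' attribute `undefined = TRUE`, and such pairs never drive tagging
#' decisions.
#'
#' @param dosage_a,dosage_b aligned numeric dosage vectors.
#' @return r² in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0) {
    return(structure(0, undefined = TRUE))
  }
  min(stats::cor(a, b)^2, 1)
}

# r² matrix for a set of columns, NA-safe via pairwise complete obs;
# zero-variance columns yield 0 against everything
r2_matrix <- function(dosage) {
  v <- apply(dosage, 2, stats::var, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(dosage, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  r2[v == 0 | is.na(v), ] <- 0
  r2[, v == 0 | is.na(v)] <- 0
  diag(r2) <- 1
  r2
}

tag_prune_core <- function(pos, r2, window_bp) {
  n <- length(pos)
  tags <- integer(0)
  for (i in seq_len(n)) {
    covered <- FALSE
    if (length(tags)) {
      near <- tags[abs(pos[tags] - pos[i]) <= window_bp]
      if (length(near) && max(r2[i, near]) >= attr(r2, "threshold")) {
        covered <- TRUE
      }
    }
    if (!covered) tags <- c(tags, i)
  }
  tags
}

#' Greedy tag-SNP pruning
#'
#' SNPs are visited in (chromosome, position, snp_id) order; a SNP becomes a
#' tag unless an already-chosen tag on the same chromosome within
#' `window_bp` has r² >= `r2_threshold` with it. Deterministic given the
#' input; pruning the resulting tag set again returns it unchanged.
#'
#' @param genotypes a [genotype_matrix()].
#' @param r2_threshold tagging threshold (default 0.9).
#' @param window_bp maximum pairwise distance considered (default 500 kb).
#' @return character vector of tag SNP ids.
#' @export
tag_prune <- function(genotypes, r2_threshold = 0.9, window_bp = 500000) {
  ann <- genotypes$snps
  ord <- order(chrom_rank(ann$chrom), ann$pos, ann$snp_id)
  tags <- character(0)
  for (ch in unique(ann$chrom[ord])) {
    idx <- ord[ann$chrom[ord] == ch]
    if (length(idx) == 1) { tags <- c(tags, ann$snp_id[idx]); next }
    r2 <- r2_matrix(genotypes$dosage[, idx, drop = FALSE])
    attr(r2, "threshold") <- r2_threshold
    keep <- tag_prune_core(ann$pos[idx], r2, window_bp)
    tags <- c(tags, ann$snp_id[idx][keep])
  }
  tags
}

chrom_rank <- function(chrom) {
  match(chrom, VALID_CHROMS)
}

#' Cis correction value: summed per-CpG tag counts
#'
#' For each CpG, the SNPs within `window` bp on the same chromosome are
#' pruned to tags at `r2_threshold` and counted; the correction value is the
#' sum of these counts over CpGs (a SNP cluster shared by several CpGs is
#' counted once per CpG).
#'
#' @param genotypes a [genotype_matrix()].
#' @param cpg_ann CpG annotation (`cpg_id`, `chrom`, `pos`).
#' @param r2_threshold tagging threshold (default 0.9).
#' @param window cis window in bp (default 500 kb).
#' @return list with `value` (the summed count) and `tags_per_cpg` (named
#'   integer vector).
#' @export
cis_correction_value <- function(genotypes, cpg_ann, r2_threshold = 0.9,
                                 window = 500000) {
  ann <- genotypes$snps
  counts <- integer(nrow(cpg_ann))
  names(counts) <- cpg_ann$cpg_id
  for (ch in unique(cpg_ann$chrom)) {
    ci <- which(cpg_ann$chrom == ch)
    si <- which(ann$chrom == ch)
    if (!length(si)) next
    o <- order(ann$pos[si], ann$snp_id[si])
    si <- si[o]
    pos <- ann$pos[si]
    r2 <- r2_matrix(genotypes$dosage[, si, drop = FALSE])
    attr(r2, "threshold") <- r2_threshold
    for (ci1 in ci) {
      inwin <- which(abs(pos - cpg_ann$pos[ci1]) <= window)
      if (!length(inwin)) next
      sub <- r2[inwin, inwin, drop = FALSE]
      attr(sub, "threshold") <- r2_threshold
      counts[ci1] <- length(tag_prune_core(pos[inwin], sub, window))
    }
  }
  list(value = sum(counts), tags_per_cpg = counts)
}

#' Trans correction value
#'
#' Total analyzed CpGs multiplied by the number of genome-wide tag SNPs,
#' minus the cis correction value. Computed in doubles (exact below 2^53).
#'
#' @param n_cpgs number of analyzed CpG sites.
#' @param n_tags_global genome-wide tag SNP count.
#' @param cis_value the cis correction value.
#' @return the trans correction value (> 0, or an error).
#' @export
trans_correction_value <- function(n_cpgs, n_tags_global, cis_value) {
  stopifnot(n_cpgs > 0, n_tags_global > 0, cis_value >= 0)
  out <- as.numeric(n_cpgs) * as.numeric(n_tags_global) - as.numeric(cis_value)
  if (out <= 0) stop("trans correction value must be positive")
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param correction_value the LD-pruned test count.
#' @return `alpha / correction_value`.
#' @export
bonferroni_threshold <- function(alpha, correction_value) {
  stopifnot(alpha > 0, alpha < 1, correction_value >= 1)
  alpha / correction_value
}

#' Correction values for the eQTL follow-up
#'
#' `mode = "cis"`: for each transcript, the supplied (significant-mQTL) SNPs
#' within `window` bp of the gene span are pruned to tags and counted; the
#' value is the per-transcript sum. `mode = "trans"`: the genome-wide pruned
#' count of the supplied SNPs multiplied by the number of transcripts.
#'
#' @param genotypes a [genotype_matrix()] restricted to the significant mQTL
#'   SNPs (must be nonempty).
#' @param transcript_ann transcript annotation (`transcript_id`, `chrom`,
#'   `start`, `end`).
#' @param mode `"cis"` or `"trans"`.
#' @param r2_threshold tagging threshold (default 0.9).
#' @param window window in bp for the cis mode and for pairwise tagging.
#' @return the correction value (double).
#' @export
eqtl_correction_values <- function(genotypes, transcript_ann,
                                   mode = c("cis", "trans"),
                                   r2_threshold = 0.9, window = 500000) {
  mode <- match.arg(mode)
  if (ncol(genotypes$dosage) == 0) stop("empty SNP subset")
  if (mode == "trans") {
    n_tags <- length(tag_prune(genotypes, r2_threshold, window))
    return(as.numeric(n_tags) * nrow(transcript_ann))
  }
  ann <- genotypes$snps
  total <- 0
  for (ch in unique(transcript_ann$chrom)) {
    ti <- which(transcript_ann$chrom == ch)
    si <- which(ann$chrom == ch)
    if (!length(si)) next
    o <- order(ann$pos[si], ann$snp_id[si])
    si <- si[o]
    pos <- ann$pos[si]
    r2 <- r2_matrix(genotypes$dosage[, si, drop = FALSE])
    for (t in ti) {
      d <- pmax(0, pmax(transcript_ann$start[t] - pos,
                        pos - transcript_ann$end[t]))
      inwin <- which(d <= window)
      if (!length(inwin)) next
      sub <- r2[inwin, inwin, drop = FALSE]
      attr(sub, "threshold") <- r2_threshold
      total <- total + length(tag_prune_core(pos[inwin], sub, window))
    }
  }
  total
}

#' Build the full multiple-testing correction plan
#'
#' Computes the per-CpG cis tag sums, the genome-wide tag count, the cis and
#' trans correction values and the resulting significance thresholds
#' (`alpha / correction value`).
#'
#' @param genotypes a [genotype_matrix()] (post-QC).
#' @param cpg_ann CpG annotation of the analyzed CpGs.
#' @param alpha family-wise error rate (default 0.05).
#' @param r2_threshold tagging threshold (default 0.9).
#' @param window cis window in bp (default 500 kb).
#' @param prune_window pairwise window for the genome-wide tag set (default
#'   500 kb, mirroring the cis window).
#' @return An object of class `correction_plan`.
#' @export
correction_plan <- function(genotypes, cpg_ann, alpha = 0.05,
                            r2_threshold = 0.9, window = 500000,
                            prune_window = 500000) {
  cis <- cis_correction_value(genotypes, cpg_ann, r2_threshold, window)
  tags <- tag_prune(genotypes, r2_threshold, prune_window)
  trans_value <- trans_correction_value(nrow(cpg_ann), length(tags),
                                        cis$value)
  structure(list(
    r2_threshold = r2_threshold, window = window, prune_window = prune_window,
    alpha = alpha,
    tags_per_feature = cis$tags_per_cpg,
    n_tags_global = length(tags), tag_ids = tags,
    cis_correction_value = cis$value,
    trans_correction_value = trans_value,
    cis_threshold = bonferroni_threshold(alpha, max(cis$value, 1)),
    trans_threshold = bonferroni_threshold(alpha, trans_value)),
    class = "correction_plan")
}

#' @export
print.correction_plan <- function(x, ...) {
  cat(sprintf(paste0(
    "correction_plan (r2 < %.2f, window %d bp, alpha %.3g):\n",
    "  cis  correction value %.0f -> threshold %.3g\n",
    "  trans correction value %.0f -> threshold %.3g\n",
    "  global tags: %d\n"),
    x$r2_threshold, as.integer(x$window), x$alpha,
    x$cis_correction_value, x$cis_threshold,
    x$trans_correction_value, x$trans_threshold, x$n_tags_global))
  invisible(x)
}
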