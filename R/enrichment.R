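# Genomic-context enrichment of significant CpGs (chromosome, gene region,
# CpG-island relation) and the SNP-CpG distance analysis.

#' Count CpGs per annotation category
#'
#' Tabulates a CpG annotation column into category counts. Multi-valued
#' entries (";"-separated, as in array manifests) contribute one count to
#' each distinct listed category.
#'
#' @param cpg_ann CpG annotation.
#' @param what `"chromosome"`, `"gene_region"` or `"island_relation"`.
#' @return named integer vector of counts.
#' @export
count_categories <- function(cpg_ann, what = c("chromosome", "gene_region",
                                               "island_relation")) {
  what <- match.arg(what)
  x <- switch(what,
              chromosome = paste0("chr", cpg_ann$chrom),
              gene_region = cpg_ann$gene_region,
              island_relation = cpg_ann$island_relation)
  per <- lapply(strsplit(as.character(x), ";", fixed = TRUE), unique)
  tab <- table(unlist(per))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Per-category enrichment of a significant set against a background
#'
#' For each category, a 2x2 table (in/out of category x significant/
#' background) is tested with a 1-df Pearson chi-squared (no continuity
#' correction); Fisher's exact test is substituted whenever any expected
#' cell is below 5. The expectation reported per category is
#' `n_sig_total * n_background_category / n_background_total`.
#'
#' @param sig_counts named counts over categories in the significant set.
#' @param background_counts named counts over the same categories in the
#'   background (all analyzed) set; every significant category must be
#'   present.
#' @param bh also attach Benjamini-Hochberg adjusted p-values (default
#'   FALSE; the per-category p-values are reported unadjusted).
#' @return data.frame of enrichment records: `category`, `n_observed`,
#'   `n_background_category`, `n_sig_total`, `n_background_total`,
#'   `expected`, `chi2`, `p`, `test`, `direction` (+ `q` when `bh`).
#' @export
chisq_enrichment <- function(sig_counts, background_counts, bh = FALSE) {
  missing_cat <- setdiff(names(sig_counts), names(background_counts))
  if (length(missing_cat)) {
    stop("category absent from background: ",
         paste(missing_cat, collapse = ", "))
  }
  cats <- names(background_counts)
  sig <- ifelse(cats %in% names(sig_counts), sig_counts[cats], 0)
  sig[is.na(sig)] <- 0
  n_sig <- sum(sig)
  n_bg <- sum(background_counts)
  if (n_bg <= 0) stop("background total must be > 0")
  rows <- lapply(seq_along(cats), function(i) {
    a <- sig[i]; b <- n_sig - a
    c_ <- background_counts[i]; d <- n_bg - c_
    expected <- n_sig * c_ / n_bg
    tab <- matrix(c(a, b, c_, d), 2, 2)
    exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_cells < 5)) {
      p <- stats::fisher.test(round(tab))$p.value
      chi2 <- NA_real_
      test <- "fisher"
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      p <- ct$p.value
      chi2 <- unname(ct$statistic)
      test <- "chisq"
    }
    direction <- if (a > expected) "over" else if (a < expected) "under" else "none"
    data.frame(category = cats[i], n_observed = unname(a),
               n_background_category = unname(c_), n_sig_total = n_sig,
               n_background_total = n_bg, expected = unname(expected),
               chi2 = chi2, p = p, test = test, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' SNP-CpG distance analysis for cis pairs
#'
#' Histograms the significant-pair distances over \[0, `window`\] at the
#' requested bin width, reports their median, and tests whether significant
#' pairs sit closer to their CpG than candidate cis pairs in general with a
#' one-sided two-sample Wilcoxon rank-sum test (alternative: significant
#' distances stochastically smaller).
#'
#' @param sig_distances distances (bp) of significant cis pairs.
#' @param all_distances distances of all candidate cis pairs.
#' @param bin_width histogram bin width in bp (e.g. 1000 or 10000).
#' @param window cis window in bp (default 500 kb).
#' @return An object of class `distance_summary`: `median_bp`, `bin_edges`,
#'   `bin_counts`, `comparison_p`, `n_sig`, `flag`.
#' @export
distance_analysis <- function(sig_distances, all_distances,
                              bin_width = 10000, window = 500000) {
  stopifnot(bin_width > 0)
  if (length(sig_distances) &&
      (any(sig_distances < 0) || any(sig_distances > window))) {
    stop("distances must lie in [0, window]")
  }
  edges <- seq(0, window + bin_width - 1e-9, by = bin_width)
  if (edges[length(edges)] < window) edges <- c(edges, window)
  if (!length(sig_distances)) {
    return(structure(list(median_bp = NA_real_, bin_edges = edges,
                          bin_counts = integer(length(edges) - 1),
                          comparison_p = NA_real_, n_sig = 0L,
                          flag = "empty_significant_set"),
                     class = "distance_summary"))
  }
  k <- length(edges) - 1L
  counts <- tabulate(pmin(findInterval(sig_distances, edges), k), nbins = k)
  p <- if (length(all_distances)) {
    suppressWarnings(stats::wilcox.test(sig_distances, all_distances,
                                        alternative = "less")$p.value)
  } else NA_real_
  structure(list(median_bp = stats::median(sig_distances), bin_edges = edges,
                 bin_counts = counts, comparison_p = p,
                 n_sig = length(sig_distances), flag = "ok"),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("distance_summary:", x$n_sig, "significant pairs, median",
      x$median_bp, "bp; one-sided rank-test p =",
      format(x$comparison_p, digits = 3), "\n")
  invisible(x)
}

#' Convert a distance summary to a writable histogram table
#' @param summary a `distance_summary`.
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
distance_summary_table <- function(summary) {
  k <- length(summary$bin_counts)
  data.frame(bin_start = summary$bin_edges[seq_len(k)],
             bin_end = summary$bin_edges[seq_len(k) + 1],
             count = summary$bin_counts)
}
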