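# LD-proxy expansion and set-overlap bookkeeping against external SNP/CpG
# lists. Proxy LD is computed from the cohort's own genotypes (parameters
# r² > 0.8 within 500 kb of the query SNP); catalog matching is by SNP id.

#' Expand query SNPs to their LD proxies
#'
#' For each query SNP, returns every SNP on the same chromosome within
#' `window_bp` whose dosage r² with the query strictly exceeds `r2_min`,
#' always including the query itself. A query absent from the genotypes is
#' flagged and gets an empty proxy set.
#'
#' @param query_snps character vector of SNP ids.
#' @param genotypes a [genotype_matrix()].
#' @param r2_min proxy threshold, strict (default 0.8).
#' @param window_bp distance limit from the query SNP (default 500 kb).
#' @return named list mapping each query to its proxy id vector; attribute
#'   `not_found` lists queries absent from the genotypes.
#' @export
proxy_expand <- function(query_snps, genotypes, r2_min = 0.8,
                         window_bp = 500000) {
  ann <- genotypes$snps
  qi <- match(query_snps, ann$snp_id)
  out <- stats::setNames(vector("list", length(query_snps)), query_snps)
  for (k in seq_along(query_snps)) {
    i <- qi[k]
    if (is.na(i)) { out[[k]] <- character(0); next }
    near <- which(ann$chrom == ann$chrom[i] &
                    abs(ann$pos - ann$pos[i]) <= window_bp)
    r2 <- vapply(near, function(j) {
      if (j == i) 1 else as.numeric(ld_r2(genotypes$dosage[, i],
                                          genotypes$dosage[, j]))
    }, numeric(1))
    out[[k]] <- ann$snp_id[near[r2 > r2_min | near == i]]
  }
  attr(out, "not_found") <- query_snps[is.na(qi)]
  out
}

#' Overlap of mQTL SNPs with a GWAS-catalog-style table
#'
#' A query SNP overlaps the catalog if it, or any of its LD proxies, matches
#' a catalog SNP id. Percentages are reported against the query set size and
#' against the number of unique catalog SNPs. The catalog is expected to be
#' restricted upstream to the traits of interest (at the source's
#' significance convention, e.g. p < 1e-5).
#'
#' @param mqtl_snps character vector of (unique) query SNP ids.
#' @param catalog data.frame with `snp_id` (and typically `trait`, `p`).
#' @param proxies optional proxy map from [proxy_expand()]; `NULL` means
#'   direct matching only.
#' @return An object of class `overlap_report` with counts, percentages and
#'   per-hit provenance (`direct` or `proxy`).
#' @export
catalog_overlap <- function(mqtl_snps, catalog, proxies = NULL) {
  mqtl_snps <- unique(mqtl_snps)
  cat_ids <- unique(catalog$snp_id)
  n_query <- length(mqtl_snps)
  n_reference <- length(cat_ids)
  direct <- mqtl_snps %in% cat_ids
  proxy_hit <- rep(FALSE, n_query)
  if (!is.null(proxies)) {
    for (k in seq_len(n_query)) {
      if (direct[k]) next
      pr <- proxies[[mqtl_snps[k]]]
      if (!is.null(pr) && any(pr %in% cat_ids)) proxy_hit[k] <- TRUE
    }
  }
  idx <- which(direct | proxy_hit)
  hits <- data.frame(
    snp_id = mqtl_snps[idx],
    provenance = ifelse(direct[idx], "direct", "proxy"),
    stringsAsFactors = FALSE)
  n_direct <- sum(direct)
  n_proxy <- sum(proxy_hit)
  n_total <- n_direct + n_proxy
  structure(list(
    n_query = n_query, n_reference = n_reference,
    n_direct_overlap = n_direct, n_proxy_overlap = n_proxy,
    n_total_overlap = n_total,
    pct_of_query = if (n_query > 0) 100 * n_total / n_query else 0,
    pct_of_reference = if (n_reference > 0) 100 * n_total / n_reference else 0,
    hits = hits), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(paste0(
    "overlap_report: %d / %d query SNPs overlap (%d direct + %d proxy)\n",
    "  %.2f%% of query set, %.1f%% of %d reference SNPs\n"),
    x$n_total_overlap, x$n_query, x$n_direct_overlap, x$n_proxy_overlap,
    x$pct_of_query, x$pct_of_reference, x$n_reference))
  invisible(x)
}

#' Exact intersection of two CpG id sets
#'
#' @param set_a,set_b character vectors of CpG ids (deduplicated
#'   internally).
#' @return list with `n_a`, `n_b`, `n_intersection`, `members`.
#' @export
cpg_set_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  members <- intersect(a, b)
  list(n_a = length(a), n_b = length(b),
       n_intersection = length(members), members = members)
}
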