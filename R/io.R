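# Readers and writers for every table the pipeline touches. All files are
# plain headered TSV; numeric output uses %.17g so that write -> read is the
# identity on doubles and repeated writes are byte-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a data.frame as full-precision TSV
#'
#' Column order is preserved; doubles are rendered with 17 significant digits
#' so a read-back reproduces them exactly and repeated writes of the same
#' records are byte-for-byte identical.
#'
#' @param df data.frame of records of one homogeneous type.
#' @param path output path.
#' @param na token used for missing values (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path, na = "NA") {
  df <- as.data.frame(df)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = na,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# ---- genotypes ---------------------------------------------------------------

parse_dosage_tokens <- function(raw, sample_ids, snp_ids, path) {
  ok <- raw %in% c("0", "1", "2")
  missing_tok <- is.na(raw) | raw %in% c("NA", "")
  bad <- !(ok | missing_tok)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid dosage token '", raw[idx[1], idx[2]], "' at sample '",
         sample_ids[idx[1]], "', SNP '", snp_ids[idx[2]], "' in ", path)
  }
  n_missing <- sum(missing_tok)
  if (n_missing > 0) {
    message("read_genotypes: ", n_missing, " missing dosage call(s) in ", path)
  }
  d <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  rownames(d) <- sample_ids
  colnames(d) <- snp_ids
  d
}

#' Read a genotype matrix
#'
#' Two text layouts are supported: `dosage_tsv` (a headered TSV with a
#' `sample_id` column followed by one 0/1/2/NA dosage column per SNP, plus a
#' companion annotation TSV) and `plink_text` (a .ped/.map pair; `path` is the
#' .ped file and `annotation` the .map file; the minor allele is determined
#' from the data and missing alleles are coded 0).
#'
#' @param path primary genotype file.
#' @param format `"dosage_tsv"` or `"plink_text"`.
#' @param annotation annotation TSV with columns `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele` and optionally `maf` (dosage_tsv), or the .map
#'   file (plink_text). For dosage_tsv with no `maf` column the MAF is
#'   computed from the dosages.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "plink_text"),
                           annotation) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    tab <- read_tsv(path, colClasses = "character")
    if (!"sample_id" %in% names(tab)) stop("dosage TSV must have a sample_id column")
    sample_ids <- tab$sample_id
    snp_ids <- setdiff(names(tab), "sample_id")
    if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in ", path)
    raw <- as.matrix(tab[snp_ids])
    dosage <- parse_dosage_tokens(raw, sample_ids, snp_ids, path)
    ann <- read_tsv(annotation)
    ann <- ann[match(snp_ids, ann$snp_id), , drop = FALSE]
    if (anyNA(ann$snp_id)) stop("annotation is missing SNPs present in ", path)
    if (!"maf" %in% names(ann)) ann$maf <- dosage_maf(dosage)
    genotype_matrix(dosage, ann)
  } else {
    read_plink_text(path, annotation)
  }
}

dosage_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("file not found: ", ped_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop(".map must have chrom, snp_id, cM, pos columns")
  names(map)[1:4] <- c("chrom", "snp_id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n_snps <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snps) {
    stop(".ped has ", ncol(ped), " columns; expected ", 6 + 2 * n_snps)
  }
  sample_ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_snps) - 1])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_snps)])
  dosage <- matrix(NA_real_, nrow(ped), n_snps,
                   dimnames = list(sample_ids, map$snp_id))
  ref <- alt <- character(n_snps)
  for (j in seq_len(n_snps)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    lev <- sort(unique(obs))
    if (length(lev) > 2) stop("SNP ", map$snp_id[j], " has >2 alleles")
    if (length(lev) == 0) lev <- c("N", "N")
    if (length(lev) == 1) lev <- c(lev, lev)
    # minor = less frequent allele; ties broken alphabetically (lev sorted)
    cnt <- c(sum(obs == lev[1]), sum(obs == lev[2]))
    minor <- if (cnt[2] <= cnt[1]) lev[2] else lev[1]
    major <- setdiff(lev, minor)[1]
    if (is.na(major)) major <- minor
    ok <- a1[, j] != "0" & a2[, j] != "0"
    dosage[ok, j] <- (a1[ok, j] == minor) + (a2[ok, j] == minor)
    ref[j] <- major
    alt[j] <- minor
  }
  ann <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                    ref_allele = ref, alt_allele = alt,
                    maf = dosage_maf(dosage), stringsAsFactors = FALSE)
  ann$maf[ann$maf == 0] <- NA  # monomorphic: MAF undefined under (0, 0.5]
  genotype_matrix(dosage, ann)
}

#' Write a genotype matrix as dosage TSV plus annotation TSV
#'
#' @param geno a [genotype_matrix()].
#' @param path dosage TSV path.
#' @param annotation annotation TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, annotation) {
  df <- data.frame(sample_id = rownames(geno$dosage),
                   geno$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  # dosages are small integers; render without exponent
  for (j in seq_along(df)[-1]) df[[j]] <- as.character(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, eol = "\n")
  write_results(geno$snps, annotation)
  invisible(path)
}

# ---- feature matrices --------------------------------------------------------

read_value_matrix <- function(path) {
  tab <- read_tsv(path)
  if (!"sample_id" %in% names(tab)) stop("matrix TSV must have a sample_id column")
  ids <- tab$sample_id
  m <- as.matrix(tab[setdiff(names(tab), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_value_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m),
                   apply(m, 2, fmt_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read one of the pipeline's typed tables
#'
#' Dispatcher over the non-genotype formats: `methylation` and `expression`
#' need a companion annotation TSV; `phenotype`, `sumstats` and `catalog` are
#' single TSVs. Enum fields are validated against the declared vocabularies.
#'
#' @param path data TSV (for matrices: `sample_id` column + one column per
#'   feature).
#' @param kind one of `"methylation"`, `"expression"`, `"phenotype"`,
#'   `"sumstats"`, `"catalog"`.
#' @param annotation annotation TSV (methylation/expression only).
#' @param scale methylation scale, `"M"` or `"beta"`.
#' @return The corresponding typed container.
#' @export
read_matrix_tsv <- function(path, kind = c("methylation", "expression",
                                           "phenotype", "sumstats", "catalog"),
                            annotation = NULL, scale = "M") {
  kind <- match.arg(kind)
  switch(kind,
    methylation = {
      m <- read_value_matrix(path)
      ann <- read_tsv(annotation)
      ann <- ann[match(colnames(m), ann$cpg_id), , drop = FALSE]
      if (anyNA(ann$cpg_id)) stop("annotation is missing CpGs present in ", path)
      methylation_matrix(m, ann, scale = scale)
    },
    expression = {
      m <- read_value_matrix(path)
      ann <- read_tsv(annotation)
      ann <- ann[match(colnames(m), ann$transcript_id), , drop = FALSE]
      if (anyNA(ann$transcript_id)) stop("annotation is missing transcripts present in ", path)
      expression_matrix(m, ann)
    },
    phenotype = {
      tab <- read_tsv(path, na.strings = c("", "NA"))
      phenotype_table(tab)
    },
    sumstats = summary_stats_table(read_tsv(path)),
    catalog = {
      tab <- read_tsv(path)
      need <- c("snp_id", "trait", "p")
      miss <- setdiff(need, names(tab))
      if (length(miss)) stop("catalog missing column(s): ",
                             paste(miss, collapse = ", "))
      tab
    }
  )
}

#' Write a methylation matrix (values + annotation)
#' @param meth a [methylation_matrix()].
#' @param path values TSV path.
#' @param annotation annotation TSV path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(meth, path, annotation) {
  write_value_matrix(meth$values, path)
  write_results(meth$cpgs, annotation)
  invisible(path)
}

#' Write an expression matrix (values + annotation)
#' @param expr an [expression_matrix()].
#' @param path values TSV path.
#' @param annotation annotation TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, annotation) {
  write_value_matrix(expr$values, path)
  write_results(expr$transcripts, annotation)
  invisible(path)
}

#' Write a phenotype table (missing values rendered as empty strings)
#' @param pheno a [phenotype_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  write_results(as.data.frame(pheno), path, na = "")
}
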