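# Typed containers shared by every stage of the pipeline.
#
# Conventions: coordinates are 1-based and inclusive; all distances are
# |pos_a - pos_b| in bp; chromosome labels are stored without a "chr" prefix;
# the missing-dosage token is "NA" and the missing-phenotype token is the
# empty string.

VALID_CHROMS <- c(as.character(1:22), "X", "Y")

GENE_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR",
                  "Intergenic")

ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")

#' Trait registry for the metabolic phenotype analyses
#'
#' Enumerates the metabolic traits the pipeline knows about, whether the
#' SNP-phenotype model additionally adjusts for BMI (glycaemic traits only;
#' BMI is never a covariate when BMI or WHR is the response), and whether the
#' trait is natural-log transformed before analysis (fasting insulin, HOMA-B
#' and HOMA-IR).
#'
#' @return A data.frame with columns `trait`, `bmi_covariate`, `log_transform`.
#' @export
trait_registry <- function() {
  data.frame(
    trait = c("fasting_glucose", "fasting_insulin", "homa_b", "homa_ir",
              "hba1c", "cholesterol", "triglycerides", "hdl", "ldl",
              "bmi", "whr"),
    bmi_covariate = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    log_transform = c(FALSE, TRUE, TRUE, TRUE, FALSE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  bad <- !chrom %in% VALID_CHROMS
  if (any(bad)) {
    stop("invalid chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  }
  chrom
}

#' Validate a SNP annotation table
#'
#' @param ann data.frame with columns `snp_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele` (the minor allele) and `maf` in (0, 0.5].
#' @return The validated annotation (chromosomes normalized).
#' @export
snp_annotation <- function(ann) {
  need <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele", "maf")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("snp annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$snp_id)) {
    stop("duplicate SNP ids: ",
         paste(utils::head(unique(ann$snp_id[duplicated(ann$snp_id)]), 5),
               collapse = ", "))
  }
  ann$chrom <- normalize_chrom(ann$chrom)
  ann$pos <- as.numeric(ann$pos)
  if (any(ann$pos < 1)) stop("SNP positions must be >= 1")
  ok_maf <- is.na(ann$maf) | (ann$maf > 0 & ann$maf <= 0.5)
  if (!all(ok_maf)) stop("maf must lie in (0, 0.5]")
  ann[need]
}

#' Validate a CpG probe annotation table
#'
#' `gene_region` and `island_relation` may be multi-valued with ";" separators
#' (as in array manifests, e.g. "Body;TSS1500"); every token must come from
#' the declared vocabulary.
#'
#' @param ann data.frame with columns `cpg_id`, `chrom`, `pos`, `gene`,
#'   `gene_region`, `island_relation`.
#' @return The validated annotation.
#' @export
cpg_annotation <- function(ann) {
  need <- c("cpg_id", "chrom", "pos", "gene", "gene_region", "island_relation")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("cpg annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$cpg_id)) stop("duplicate CpG ids")
  ann$chrom <- normalize_chrom(ann$chrom)
  ann$pos <- as.numeric(ann$pos)
  ann$gene <- as.character(ann$gene)
  ann$gene[is.na(ann$gene)] <- ""
  if (any(ann$pos < 1)) stop("CpG positions must be >= 1")
  check_vocab(ann$gene_region, GENE_REGIONS, "gene_region")
  check_vocab(ann$island_relation, ISLAND_RELATIONS, "island_relation")
  ann[need]
}

check_vocab <- function(x, vocab, what) {
  toks <- unlist(strsplit(as.character(x), ";", fixed = TRUE))
  toks <- toks[nzchar(toks)]
  bad <- setdiff(unique(toks), vocab)
  if (length(bad)) {
    stop("unknown ", what, " token(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a genotype matrix container
#'
#' @param dosage numeric matrix, samples in rows and SNPs in columns; values
#'   restricted to 0, 1, 2 or NA (additive minor-allele dosage).
#' @param snps SNP annotation (see [snp_annotation()]), one row per column of
#'   `dosage`, in column order.
#' @return An object of class `genotype_matrix` with elements `dosage` and
#'   `snps`.
#' @export
genotype_matrix <- function(dosage, snps) {
  snps <- snp_annotation(snps)
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(snps)) {
    stop("dosage has ", ncol(dosage), " columns but annotation has ",
         nrow(snps), " SNPs")
  }
  if (is.null(rownames(dosage))) stop("dosage must carry sample ids as rownames")
  colnames(dosage) <- snps$snp_id
  v <- dosage[!is.na(dosage)]
  if (!all(v %in% c(0, 1, 2))) {
    bad <- which(!is.na(dosage) & !(dosage %in% c(0, 1, 2)), arr.ind = TRUE)[1, ]
    stop("invalid dosage value at sample '", rownames(dosage)[bad[1]],
         "', SNP '", colnames(dosage)[bad[2]], "': ",
         dosage[bad[1], bad[2]], " (must be 0, 1, 2 or NA)")
  }
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs;", sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Construct a methylation matrix container
#'
#' @param values numeric matrix, samples x CpGs. On the `beta` scale values
#'   must lie in \[0, 1\]; on the `M` scale any finite real is allowed.
#' @param cpgs CpG annotation (see [cpg_annotation()]).
#' @param scale `"M"` (log2 methylated/unmethylated intensity ratio) or
#'   `"beta"` (methylation fraction).
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(values, cpgs, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  cpgs <- cpg_annotation(cpgs)
  values <- as.matrix(values)
  if (ncol(values) != nrow(cpgs)) stop("values/annotation dimension mismatch")
  if (is.null(rownames(values))) stop("values must carry sample ids as rownames")
  colnames(values) <- cpgs$cpg_id
  fin <- values[!is.na(values)]
  if (scale == "beta" && any(fin < 0 | fin > 1)) {
    stop("beta-scale methylation values must lie in [0, 1]")
  }
  if (scale == "M" && any(!is.finite(fin))) {
    stop("M-scale methylation values must be finite")
  }
  structure(list(values = values, cpgs = cpgs, scale = scale),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "CpGs on the", x$scale, "scale\n")
  invisible(x)
}

#' Construct an expression matrix container
#'
#' @param values numeric matrix, samples x transcripts (normalized intensity
#'   scale).
#' @param transcripts data.frame with `transcript_id`, `chrom`, `start`,
#'   `end`, `gene`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, transcripts) {
  need <- c("transcript_id", "chrom", "start", "end", "gene")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) stop("transcript annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript ids")
  transcripts$chrom <- normalize_chrom(transcripts$chrom)
  transcripts$start <- as.numeric(transcripts$start)
  transcripts$end <- as.numeric(transcripts$end)
  if (any(transcripts$start > transcripts$end)) stop("transcript start > end")
  values <- as.matrix(values)
  if (ncol(values) != nrow(transcripts)) stop("values/annotation dimension mismatch")
  if (is.null(rownames(values))) stop("values must carry sample ids as rownames")
  if (any(!is.finite(values[!is.na(values)]))) stop("expression values must be finite")
  colnames(values) <- transcripts$transcript_id
  structure(list(values = values, transcripts = transcripts[need]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "transcripts\n")
  invisible(x)
}

#' Construct a phenotype/covariate table
#'
#' @param df data.frame with `sample_id`, `age`, `bmi`, `cohort`, optionally
#'   `batch`, plus trait columns named after [trait_registry()] entries.
#'   Missing values are allowed in traits.
#' @param cohorts declared finite set of cohort labels; defaults to the labels
#'   present.
#' @return An object of class `phenotype_table` (a validated data.frame).
#' @export
phenotype_table <- function(df, cohorts = NULL) {
  need <- c("sample_id", "age", "bmi", "cohort")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (is.null(cohorts)) cohorts <- sort(unique(as.character(df$cohort)))
  bad <- setdiff(unique(as.character(df$cohort)), cohorts)
  if (length(bad)) stop("cohort label(s) outside declared set: ",
                        paste(bad, collapse = ", "))
  extra <- setdiff(names(df), c(need, "batch"))
  unknown <- setdiff(extra, trait_registry()$trait)
  if (length(unknown)) stop("unknown trait column(s): ",
                            paste(unknown, collapse = ", "))
  attr(df, "cohorts") <- cohorts
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Construct an external summary-statistics table
#'
#' One row per (SNP, trait) lookup from a consortium-style source: the effect
#' allele, the sign of the reported effect, and the reported p-value.
#'
#' @param df data.frame with `snp_id`, `effect_allele`, `effect_sign`
#'   (+1 or -1), `p` in \[0, 1\]; an optional `trait` column restricts lookups.
#' @return An object of class `summary_stats_table`.
#' @export
summary_stats_table <- function(df) {
  need <- c("snp_id", "effect_allele", "effect_sign", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("summary stats missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$effect_sign %in% c(-1, 1))) stop("effect_sign must be +1 or -1")
  if (any(df$p < 0 | df$p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  class(df) <- c("summary_stats_table", "data.frame")
  df
}
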