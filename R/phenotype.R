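# SNP-phenotype association with conditional covariates, trait transforms,
# and the sign-concordant external replication filter.

#' Natural-log transform the designated traits
#'
#' Applies `log()` to fasting insulin, HOMA-B and HOMA-IR only (per the
#' trait registry); all other traits are untouched. Missing values pass
#' through; a nonpositive value in a targeted trait is an error naming the
#' sample.
#'
#' @param phenotypes a [phenotype_table()].
#' @return The transformed table, with attribute `log_transformed` listing
#'   the traits transformed.
#' @export
transform_traits <- function(phenotypes) {
  reg <- trait_registry()
  targets <- intersect(reg$trait[reg$log_transform], names(phenotypes))
  for (tr in targets) {
    v <- phenotypes[[tr]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      stop("nonpositive ", tr, " for sample(s): ",
           paste(phenotypes$sample_id[bad], collapse = ", "))
    }
    phenotypes[[tr]] <- log(v)
  }
  attr(phenotypes, "log_transformed") <- targets
  phenotypes
}

#' SNP-phenotype association for one trait
#'
#' OLS of the trait on \[intercept, dosage, covariates\] as in [fit_qtl()].
#' Age and sub-cohort are covariates in every model; BMI is added iff the
#' trait is one of the glycaemic traits flagged in [trait_registry()]
#' (fasting glucose, fasting insulin, HOMA-IR, HOMA-B, HbA1c), and never
#' when BMI or WHR is the response.
#'
#' @param phenotypes a [phenotype_table()] (already trait-transformed if
#'   desired; see [transform_traits()]).
#' @param genotypes a [genotype_matrix()] with samples aligned to
#'   `phenotypes` by `sample_id`.
#' @param snp_id the SNP to test.
#' @param trait the trait name (must be in the registry).
#' @return one-row data.frame: `snp_id`, `trait`, `beta`, `se`, `t_stat`,
#'   `p`, `n_used`, `covariates_used`, `internal_pass` (p < 0.05).
#' @export
assoc_phenotype <- function(phenotypes, genotypes, snp_id, trait) {
  reg <- trait_registry()
  row <- match(trait, reg$trait)
  if (is.na(row)) stop("trait not in registry: ", trait)
  if (!trait %in% names(phenotypes)) stop("trait column absent: ", trait)
  j <- match(snp_id, genotypes$snps$snp_id)
  if (is.na(j)) stop("unknown SNP: ", snp_id)
  idx <- match(phenotypes$sample_id, rownames(genotypes$dosage))
  if (anyNA(idx)) stop("phenotype samples missing from genotypes")
  y <- phenotypes[[trait]]
  if (mean(is.na(y)) > 0.5) {
    warning("trait ", trait, " missing for >50% of samples")
  }
  covs <- data.frame(age = phenotypes$age, cohort = phenotypes$cohort,
                     stringsAsFactors = FALSE)
  use_bmi <- reg$bmi_covariate[row]
  if (use_bmi) covs$bmi <- phenotypes$bmi
  fit <- fit_qtl(y, genotypes$dosage[idx, j], covs)
  data.frame(snp_id = snp_id, trait = trait, beta = fit$beta, se = fit$se,
             t_stat = fit$t_stat, p = fit$p, n_used = fit$n_used,
             covariates_used = paste(names(covs), collapse = ","),
             internal_pass = !is.na(fit$p) && fit$p < 0.05,
             stringsAsFactors = FALSE)
}

#' Sign-concordant external replication filter
#'
#' Looks each internal record up in an external summary-statistics table
#' (matched on `snp_id`, and on `trait` when the external table carries a
#' trait column), harmonizes the external effect sign to the internal
#' effect (minor/alt) allele -- flipping it when the external effect allele
#' is the other allele -- and flags a record replicated iff internal
#' p < 0.05, external p < 0.05, and the signs agree (all strict).
#' Strand-ambiguous SNPs (A/T or C/G) are flagged but retained. SNPs absent
#' from the external table get status `"not_found"`.
#'
#' @param records data.frame of internal results with `snp_id`, `trait`,
#'   `beta`, `p`.
#' @param external a [summary_stats_table()].
#' @param snp_ann SNP annotation supplying `ref_allele`/`alt_allele` for
#'   harmonization.
#' @return `records` with columns `external_sign`, `external_p`,
#'   `replicated`, `status`, `strand_ambiguous` appended.
#' @export
replicate_filter <- function(records, external, snp_ann) {
  ai <- match(records$snp_id, snp_ann$snp_id)
  if (anyNA(ai)) stop("record SNP(s) missing from annotation")
  ref <- toupper(snp_ann$ref_allele[ai])
  alt <- toupper(snp_ann$alt_allele[ai])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  strand_ambiguous <- ref == unname(comp[alt])
  if ("trait" %in% names(external) && "trait" %in% names(records)) {
    ei <- match(paste(records$snp_id, records$trait),
                paste(external$snp_id, external$trait))
  } else {
    ei <- match(records$snp_id, external$snp_id)
  }
  ext_allele <- toupper(external$effect_allele[ei])
  ext_sign <- external$effect_sign[ei]
  ext_p <- external$p[ei]
  flip <- !is.na(ext_allele) & ext_allele == ref
  match_alt <- !is.na(ext_allele) & ext_allele == alt
  ext_sign[flip] <- -ext_sign[flip]
  status <- ifelse(is.na(ei), "not_found",
                   ifelse(!(flip | match_alt), "allele_mismatch", "found"))
  internal_sign <- sign(records$beta)
  replicated <- status == "found" &
    !is.na(records$p) & records$p < 0.05 &
    !is.na(ext_p) & ext_p < 0.05 &
    internal_sign == ext_sign
  replicated[is.na(replicated)] <- FALSE
  records$external_sign <- ext_sign
  records$external_p <- ext_p
  records$replicated <- replicated
  records$status <- status
  records$strand_ambiguous <- strand_ambiguous
  records
}
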