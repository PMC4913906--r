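# End-to-end orchestration: stage order is QC -> mQTL -> {eQTL, phenotype}
# -> CIT -> enrichment/overlap, with the eQTL and phenotype stages consuming
# only SNPs significant after the LD-aware correction (cis and trans kept
# separate throughout). Every stage writes TSV outputs plus a JSON manifest
# (input hashes, parameters, seed, package version); identical manifests
# imply byte-identical outputs.

#' Default pipeline configuration
#'
#' @return nested list of parameters: `simulation` (passed to
#'   [default_simulation_config()]), `qc`, `scan` (cis window, tagging r²,
#'   alpha, trans output threshold), `expression_window`, `cit`, `overlap`.
#' @export
default_pipeline_config <- function() {
  list(
    simulation = list(),
    qc = list(max_missing = 0.05, hwe_alpha = 0.001, min_maf = 0.05,
              min_call_rate = 0.98),
    scan = list(window = 500000, r2_threshold = 0.9, alpha = 0.05,
                prune_window = 500000, p_keep_trans = 1e-4,
                covariates = c("age", "bmi", "cohort")),
    expression_window = list(upstream = 500000, downstream = 100000,
                             fdr = 0.05),
    cit = list(B = 1000),
    overlap = list(r2_min = 0.8, window = 500000)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [default_pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(cfg$scan$alpha) &&
      (cfg$scan$alpha <= 0 || cfg$scan$alpha >= 1)) {
    stop("alpha must lie in (0, 1)")
  }
  cfg
}

stage_path <- function(out_dir, name) file.path(out_dir, name)

require_inputs <- function(out_dir, files, needed_stage) {
  paths <- stage_path(out_dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop("missing upstream output(s) ", paste(missing, collapse = ", "),
         "; run stage '", needed_stage, "' first")
  }
  invisible(paths)
}

write_manifest <- function(out_dir, stage, inputs, params, seed, outputs) {
  md5_by_name <- function(files) {
    h <- tools::md5sum(stage_path(out_dir, files))
    names(h) <- files
    as.list(h)
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("methex")),
    seed = seed,
    inputs = md5_by_name(inputs),
    params = params,
    outputs = md5_by_name(outputs))
  jsonlite::write_json(manifest, stage_path(out_dir,
                                            paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

load_stage_inputs <- function(out_dir, qc = TRUE) {
  suffix <- if (qc) "_qc" else ""
  geno <- read_genotypes(stage_path(out_dir, paste0("genotypes", suffix, ".tsv")),
                         "dosage_tsv",
                         stage_path(out_dir, paste0("snp_annotation", suffix, ".tsv")))
  meth <- read_matrix_tsv(stage_path(out_dir, paste0("methylation", suffix, ".tsv")),
                          "methylation",
                          stage_path(out_dir, paste0("cpg_annotation", suffix, ".tsv")))
  pheno <- read_matrix_tsv(stage_path(out_dir, "phenotypes.tsv"), "phenotype")
  # align every table to the genotype sample order (QC may drop samples)
  ids <- rownames(geno$dosage)
  meth$values <- meth$values[ids, , drop = FALSE]
  pheno <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  class(pheno) <- c("phenotype_table", "data.frame")
  list(genotypes = geno, methylation = meth, phenotypes = pheno)
}

scan_covariates <- function(pheno, covariate_names) {
  as.data.frame(pheno)[, covariate_names, drop = FALSE]
}

subset_cohorts <- function(objs, cohorts) {
  if (is.null(cohorts)) return(objs)
  keep <- objs$phenotypes$cohort %in% cohorts
  if (!any(keep)) stop("no samples left after cohort subset")
  ids <- objs$phenotypes$sample_id[keep]
  objs$phenotypes <- objs$phenotypes[keep, , drop = FALSE]
  class(objs$phenotypes) <- c("phenotype_table", "data.frame")
  objs$genotypes$dosage <- objs$genotypes$dosage[ids, , drop = FALSE]
  objs$methylation$values <- objs$methylation$values[ids, , drop = FALSE]
  objs
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (generate and write the synthetic cohort), `qc`
#' (genotype and probe filters), `mqtl` (correction plan + cis/trans scans
#' and significant subsets), `eqtl` (expression follow-up of significant
#' mQTL SNPs, plus the methylation-expression window scan), `pheno`
#' (SNP-phenotype association with external replication), `cit` (causal
#' inference test over nominated triples), `enrich` (genomic-context
#' enrichment and distance analysis), `overlap` (LD-proxy catalog overlap),
#' or `all` (the full order). Dependent stages error when upstream outputs
#' are absent, naming the stage to run first.
#'
#' @param name stage name.
#' @param config configuration list from [read_pipeline_config()].
#' @param out_dir output directory (created if needed); all stages read and
#'   write here.
#' @param seed integer overriding the simulation seed and seeding the CIT
#'   permutations (default: the simulation config's seed).
#' @param no_bmi_covariate drop BMI from the mQTL scan covariates
#'   (sensitivity switch).
#' @param cohorts restrict the mQTL scan to these sub-cohort labels
#'   (sensitivity switch; `NULL` = all).
#' @return invisibly, the stage manifest (or list of manifests for `all`).
#' @export
run_stage <- function(name = c("simulate", "qc", "mqtl", "eqtl", "pheno",
                               "cit", "enrich", "overlap", "all"),
                      config = default_pipeline_config(), out_dir,
                      seed = NULL, no_bmi_covariate = FALSE, cohorts = NULL) {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "all") {
    stages <- c("simulate", "qc", "mqtl", "eqtl", "pheno", "cit", "enrich",
                "overlap")
    return(invisible(lapply(stages, run_stage, config = config,
                            out_dir = out_dir, seed = seed,
                            no_bmi_covariate = no_bmi_covariate,
                            cohorts = cohorts)))
  }
  switch(name,
    simulate = stage_simulate(config, out_dir, seed),
    qc = stage_qc(config, out_dir, seed),
    mqtl = stage_mqtl(config, out_dir, seed, no_bmi_covariate, cohorts),
    eqtl = stage_eqtl(config, out_dir, seed, no_bmi_covariate, cohorts),
    pheno = stage_pheno(config, out_dir, seed),
    cit = stage_cit(config, out_dir, seed),
    enrich = stage_enrich(config, out_dir, seed),
    overlap = stage_overlap(config, out_dir, seed))
}

stage_simulate <- function(config, out_dir, seed) {
  sim_args <- config$simulation
  if (!is.null(seed)) sim_args$seed <- seed
  sim_cfg <- do.call(default_simulation_config, sim_args)
  cohort <- simulate_cohort(sim_cfg)
  write_genotypes(cohort$genotypes, stage_path(out_dir, "genotypes.tsv"),
                  stage_path(out_dir, "snp_annotation.tsv"))
  write_methylation(cohort$methylation, stage_path(out_dir, "methylation.tsv"),
                    stage_path(out_dir, "cpg_annotation.tsv"))
  if (!is.null(cohort$expression)) {
    write_expression(cohort$expression, stage_path(out_dir, "expression.tsv"),
                     stage_path(out_dir, "transcript_annotation.tsv"))
  }
  write_phenotypes(cohort$phenotypes, stage_path(out_dir, "phenotypes.tsv"))
  write_results(as.data.frame(cohort$sumstats),
                stage_path(out_dir, "sumstats.tsv"))
  write_results(cohort$catalog, stage_path(out_dir, "catalog.tsv"))
  outputs <- c("genotypes.tsv", "snp_annotation.tsv", "methylation.tsv",
               "cpg_annotation.tsv", "phenotypes.tsv", "sumstats.tsv",
               "catalog.tsv")
  if (!is.null(cohort$expression)) {
    outputs <- c(outputs, "expression.tsv", "transcript_annotation.tsv")
  }
  write_manifest(out_dir, "simulate", character(0),
                 params = sim_cfg[c("n_samples", "n_snps", "n_cpgs",
                                    "n_transcripts", "ld_block_size",
                                    "within_block_r", "seed")],
                 seed = sim_cfg$seed, outputs = outputs)
}

stage_qc <- function(config, out_dir, seed) {
  require_inputs(out_dir, c("genotypes.tsv", "snp_annotation.tsv",
                            "methylation.tsv", "cpg_annotation.tsv"),
                 "simulate")
  geno <- read_genotypes(stage_path(out_dir, "genotypes.tsv"), "dosage_tsv",
                         stage_path(out_dir, "snp_annotation.tsv"))
  meth <- read_matrix_tsv(stage_path(out_dir, "methylation.tsv"),
                          "methylation",
                          stage_path(out_dir, "cpg_annotation.tsv"))
  sflt <- filter_samples(geno, config$qc$min_call_rate)
  gflt <- filter_snps(sflt$genotypes, config$qc$max_missing,
                      config$qc$hwe_alpha, config$qc$min_maf)
  pflt <- filter_probes(meth, detection_p = NULL, max_mean_detp = NULL)
  keep <- rownames(gflt$genotypes$dosage)
  vals <- pflt$methylation$values[keep, , drop = FALSE]
  # batch correction before any scan, as in array pipelines
  pheno_path <- stage_path(out_dir, "phenotypes.tsv")
  if (file.exists(pheno_path)) {
    pheno <- read_matrix_tsv(pheno_path, "phenotype")
    if ("batch" %in% names(pheno)) {
      batch <- pheno$batch[match(keep, pheno$sample_id)]
      if (!anyNA(batch) && all(table(batch) >= 2)) {
        vals <- adjust_batch(vals, batch)
      }
    }
  }
  meth_qc <- methylation_matrix(vals, pflt$methylation$cpgs,
                                scale = pflt$methylation$scale)
  write_genotypes(gflt$genotypes, stage_path(out_dir, "genotypes_qc.tsv"),
                  stage_path(out_dir, "snp_annotation_qc.tsv"))
  write_methylation(meth_qc, stage_path(out_dir, "methylation_qc.tsv"),
                    stage_path(out_dir, "cpg_annotation_qc.tsv"))
  report <- rbind(cbind(stage = "samples", qc_report_table(sflt$report)),
                  cbind(stage = "snps", qc_report_table(gflt$report)),
                  cbind(stage = "probes", qc_report_table(pflt$report)))
  write_results(report, stage_path(out_dir, "qc_report.tsv"))
  write_manifest(out_dir, "qc",
                 c("genotypes.tsv", "methylation.tsv"),
                 params = config$qc, seed = seed,
                 outputs = c("genotypes_qc.tsv", "snp_annotation_qc.tsv",
                             "methylation_qc.tsv", "cpg_annotation_qc.tsv",
                             "qc_report.tsv"))
}

stage_mqtl <- function(config, out_dir, seed, no_bmi_covariate, cohorts) {
  require_inputs(out_dir, c("genotypes_qc.tsv", "methylation_qc.tsv",
                            "phenotypes.tsv"), "qc")
  objs <- load_stage_inputs(out_dir)
  objs <- subset_cohorts(objs, cohorts)
  covs <- config$scan$covariates
  if (no_bmi_covariate) covs <- setdiff(covs, "bmi")
  C <- scan_covariates(objs$phenotypes, covs)
  plan <- correction_plan(objs$genotypes, objs$methylation$cpgs,
                          alpha = config$scan$alpha,
                          r2_threshold = config$scan$r2_threshold,
                          window = config$scan$window,
                          prune_window = config$scan$prune_window)
  cis <- scan_qtl(objs$genotypes, objs$methylation, C, "cis",
                  window = config$scan$window)
  trans <- scan_qtl(objs$genotypes, objs$methylation, C, "trans",
                    window = config$scan$window,
                    p_keep = config$scan$p_keep_trans)
  cis_sig <- cis[!is.na(cis$p) & cis$p < plan$cis_threshold, , drop = FALSE]
  trans_sig <- trans[!is.na(trans$p) & trans$p < plan$trans_threshold, ,
                     drop = FALSE]
  cpg_snps <- detect_cpg_snps(objs$genotypes$snps, objs$methylation$cpgs)
  write_results(cis, stage_path(out_dir, "mqtl_cis.tsv"))
  write_results(trans, stage_path(out_dir, "mqtl_trans.tsv"))
  write_results(cis_sig, stage_path(out_dir, "mqtl_cis_significant.tsv"))
  write_results(trans_sig, stage_path(out_dir, "mqtl_trans_significant.tsv"))
  write_results(cpg_snps, stage_path(out_dir, "cpg_snps.tsv"))
  jsonlite::write_json(
    list(r2_threshold = plan$r2_threshold, window = plan$window,
         alpha = plan$alpha, n_tags_global = plan$n_tags_global,
         cis_correction_value = plan$cis_correction_value,
         trans_correction_value = plan$trans_correction_value,
         cis_threshold = plan$cis_threshold,
         trans_threshold = plan$trans_threshold),
    stage_path(out_dir, "correction_plan.json"), auto_unbox = TRUE,
    digits = NA)
  write_manifest(out_dir, "mqtl",
                 c("genotypes_qc.tsv", "methylation_qc.tsv", "phenotypes.tsv"),
                 params = c(config$scan,
                            list(no_bmi_covariate = no_bmi_covariate,
                                 cohorts = cohorts)),
                 seed = seed,
                 outputs = c("mqtl_cis.tsv", "mqtl_trans.tsv",
                             "mqtl_cis_significant.tsv",
                             "mqtl_trans_significant.tsv", "cpg_snps.tsv",
                             "correction_plan.json"))
}

subset_genotypes <- function(geno, snp_ids) {
  keep <- geno$snps$snp_id %in% snp_ids
  genotype_matrix(geno$dosage[, keep, drop = FALSE],
                  geno$snps[keep, , drop = FALSE])
}

stage_eqtl <- function(config, out_dir, seed, no_bmi_covariate, cohorts) {
  require_inputs(out_dir, c("mqtl_cis_significant.tsv",
                            "mqtl_trans_significant.tsv"), "mqtl")
  require_inputs(out_dir, c("expression.tsv", "transcript_annotation.tsv"),
                 "simulate")
  objs <- load_stage_inputs(out_dir)
  objs$expression <- read_matrix_tsv(stage_path(out_dir, "expression.tsv"),
                                     "expression",
                                     stage_path(out_dir,
                                                "transcript_annotation.tsv"))
  objs$expression$values <-
    objs$expression$values[rownames(objs$genotypes$dosage), , drop = FALSE]
  C <- scan_covariates(objs$phenotypes, config$scan$covariates)
  cis_sig <- read_tsv(stage_path(out_dir, "mqtl_cis_significant.tsv"))
  trans_sig <- read_tsv(stage_path(out_dir, "mqtl_trans_significant.tsv"))
  out_files <- c("me_assoc.tsv")
  alpha <- config$scan$alpha
  thresholds <- list()
  for (side in c("cis", "trans")) {
    sig <- if (side == "cis") cis_sig else trans_sig
    file <- paste0("eqtl_", side, ".tsv")
    out_files <- c(out_files, file)
    if (!nrow(sig)) {
      write_results(data.frame(snp_id = character(), feature_id = character(),
                               distance = numeric(), beta = numeric(),
                               se = numeric(), t_stat = numeric(),
                               p = numeric(), n_used = integer(),
                               relation = character()),
                    stage_path(out_dir, file))
      next
    }
    sub <- subset_genotypes(objs$genotypes, unique(sig$snp_id))
    value <- eqtl_correction_values(sub, objs$expression$transcripts, side,
                                    config$scan$r2_threshold,
                                    config$scan$window)
    thr <- if (value >= 1) bonferroni_threshold(alpha, value) else alpha
    thresholds[[side]] <- list(correction_value = value, threshold = thr)
    rec <- scan_qtl(sub, objs$expression, C, side,
                    window = config$scan$window,
                    p_keep = if (side == "trans") config$scan$p_keep_trans else 1)
    rec$significant <- !is.na(rec$p) & rec$p < thr
    write_results(rec, stage_path(out_dir, file))
  }
  me <- scan_methylation_expression(objs$methylation, objs$expression, C,
                                    config$expression_window$upstream,
                                    config$expression_window$downstream,
                                    config$expression_window$fdr)
  write_results(me, stage_path(out_dir, "me_assoc.tsv"))
  jsonlite::write_json(thresholds,
                       stage_path(out_dir, "eqtl_thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "eqtl",
                 c("genotypes_qc.tsv", "expression.tsv",
                   "mqtl_cis_significant.tsv", "mqtl_trans_significant.tsv"),
                 params = config$scan, seed = seed,
                 outputs = c(out_files, "eqtl_thresholds.json"))
}

stage_pheno <- function(config, out_dir, seed) {
  require_inputs(out_dir, c("mqtl_cis_significant.tsv",
                            "mqtl_trans_significant.tsv", "sumstats.tsv"),
                 "mqtl")
  objs <- load_stage_inputs(out_dir)
  cis_sig <- read_tsv(stage_path(out_dir, "mqtl_cis_significant.tsv"))
  trans_sig <- read_tsv(stage_path(out_dir, "mqtl_trans_significant.tsv"))
  sumstats <- read_matrix_tsv(stage_path(out_dir, "sumstats.tsv"), "sumstats")
  pheno <- transform_traits(objs$phenotypes)
  snps <- unique(c(cis_sig$snp_id, trans_sig$snp_id))
  traits <- intersect(trait_registry()$trait, names(pheno))
  records <- list()
  for (s in snps) {
    for (tr in traits) {
      records[[length(records) + 1L]] <-
        assoc_phenotype(pheno, objs$genotypes, s, tr)
    }
  }
  rec <- if (length(records)) do.call(rbind, records) else
    data.frame(snp_id = character(), trait = character(), beta = numeric(),
               se = numeric(), t_stat = numeric(), p = numeric(),
               n_used = integer(), covariates_used = character(),
               internal_pass = logical(), stringsAsFactors = FALSE)
  if (nrow(rec)) {
    rec <- replicate_filter(rec, sumstats, objs$genotypes$snps)
  }
  write_results(rec, stage_path(out_dir, "phenotype_assoc.tsv"))
  write_manifest(out_dir, "pheno",
                 c("genotypes_qc.tsv", "phenotypes.tsv", "sumstats.tsv",
                   "mqtl_cis_significant.tsv", "mqtl_trans_significant.tsv"),
                 params = list(alpha = 0.05), seed = seed,
                 outputs = "phenotype_assoc.tsv")
}

stage_cit <- function(config, out_dir, seed) {
  require_inputs(out_dir, c("mqtl_cis_significant.tsv",
                            "phenotype_assoc.tsv"), "pheno")
  objs <- load_stage_inputs(out_dir)
  cis_sig <- read_tsv(stage_path(out_dir, "mqtl_cis_significant.tsv"))
  pa <- read_tsv(stage_path(out_dir, "phenotype_assoc.tsv"))
  pheno <- transform_traits(objs$phenotypes)
  # nominate triples: significant SNP-CpG pair x trait with internal p<0.05
  pa_pass <- pa[pa$internal_pass %in% TRUE, c("snp_id", "trait")]
  triples <- merge(cis_sig[, c("snp_id", "feature_id")], pa_pass,
                   by = "snp_id")
  names(triples)[names(triples) == "feature_id"] <- "cpg_id"
  triples <- triples[order(triples$snp_id, triples$cpg_id, triples$trait), ]
  base_seed <- if (is.null(seed)) 1L else as.integer(seed)
  rec <- if (nrow(triples)) {
    cit_test(triples, objs$genotypes, objs$methylation, pheno,
             B = config$cit$B, seed = base_seed)
  } else {
    data.frame(snp_id = character(), cpg_id = character(), trait = character(),
               p1 = numeric(), p2 = numeric(), p3 = numeric(), p4 = numeric(),
               p_causal = numeric(), p_reverse = numeric(),
               classification = character(), n_used = integer(),
               n_permutations = integer(), seed = integer(),
               stringsAsFactors = FALSE)
  }
  write_results(rec, stage_path(out_dir, "cit_records.tsv"))
  write_manifest(out_dir, "cit",
                 c("mqtl_cis_significant.tsv", "phenotype_assoc.tsv"),
                 params = list(B = config$cit$B), seed = base_seed,
                 outputs = "cit_records.tsv")
}

stage_enrich <- function(config, out_dir, seed) {
  require_inputs(out_dir, c("mqtl_cis.tsv", "mqtl_cis_significant.tsv",
                            "cpg_annotation_qc.tsv"), "mqtl")
  cis <- read_tsv(stage_path(out_dir, "mqtl_cis.tsv"))
  cis_sig <- read_tsv(stage_path(out_dir, "mqtl_cis_significant.tsv"))
  cpgs <- cpg_annotation(read_tsv(stage_path(out_dir, "cpg_annotation_qc.tsv")))
  sig_cpgs <- cpgs[cpgs$cpg_id %in% cis_sig$feature_id, , drop = FALSE]
  outputs <- character(0)
  for (what in c("chromosome", "gene_region", "island_relation")) {
    enr <- chisq_enrichment(count_categories(sig_cpgs, what),
                            count_categories(cpgs, what))
    file <- paste0("enrichment_", what, ".tsv")
    write_results(enr, stage_path(out_dir, file))
    outputs <- c(outputs, file)
  }
  ds <- distance_analysis(cis_sig$distance, cis$distance,
                          bin_width = 10000, window = config$scan$window)
  write_results(distance_summary_table(ds),
                stage_path(out_dir, "distance_histogram.tsv"))
  jsonlite::write_json(list(median_bp = ds$median_bp,
                            comparison_p = ds$comparison_p,
                            n_sig = ds$n_sig, flag = ds$flag),
                       stage_path(out_dir, "distance_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "enrich",
                 c("mqtl_cis.tsv", "mqtl_cis_significant.tsv",
                   "cpg_annotation_qc.tsv"),
                 params = list(bin_width = 10000), seed = seed,
                 outputs = c(outputs, "distance_histogram.tsv",
                             "distance_summary.json"))
}

stage_overlap <- function(config, out_dir, seed) {
  require_inputs(out_dir, c("mqtl_cis_significant.tsv", "catalog.tsv"),
                 "mqtl")
  objs <- load_stage_inputs(out_dir)
  cis_sig <- read_tsv(stage_path(out_dir, "mqtl_cis_significant.tsv"))
  catalog <- read_matrix_tsv(stage_path(out_dir, "catalog.tsv"), "catalog")
  snps <- unique(cis_sig$snp_id)
  proxies <- proxy_expand(snps, objs$genotypes, config$overlap$r2_min,
                          config$overlap$window)
  report <- catalog_overlap(snps, catalog, proxies)
  write_results(report$hits, stage_path(out_dir, "overlap_hits.tsv"))
  jsonlite::write_json(report[c("n_query", "n_reference", "n_direct_overlap",
                                "n_proxy_overlap", "n_total_overlap",
                                "pct_of_query", "pct_of_reference")],
                       stage_path(out_dir, "overlap_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "overlap",
                 c("mqtl_cis_significant.tsv", "catalog.tsv",
                   "genotypes_qc.tsv"),
                 params = config$overlap, seed = seed,
                 outputs = c("overlap_hits.tsv", "overlap_report.json"))
}
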