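# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes -- LD-block genotypes with a realistic MAF spectrum, additive
# SNP->methylation effects in cis and trans (including CpG-SNPs),
# SNP->expression effects, batch/cohort structure, covariate confounding, and
# genotype -> methylation -> phenotype mediation structures -- so that every
# downstream stage can be exercised without external data.
#
# Each layer draws from its own RNG stream derived from the master seed
# (seed + small offset), so layers are individually reproducible and
# regenerating one layer does not perturb another.

N_SIM_CHROMS <- 22L
SNP_SPACING <- 2000L     # bp between adjacent simulated SNPs
POS_OFFSET <- 1000000L   # first feature position on every chromosome
CPG_PHASE <- 13L         # keeps unplanted SNP-CpG distances away from {0,1}

#' Build and validate a simulation configuration
#'
#' @param n_samples,n_snps,n_cpgs,n_transcripts cohort dimensions.
#' @param ld_block_size SNPs per LD block (blocks never span chromosomes).
#' @param within_block_r target dosage correlation between SNPs of one block,
#'   in \[0, 1).
#' @param maf_range interval within (0.05, 0.5\] from which per-block minor
#'   allele frequencies are drawn.
#' @param planted_mqtls data.frame (`snp`, `cpg`, `beta`, `relation`) of
#'   additive per-allele SNP effects on CpG M-values; `relation` is the
#'   intended cis/trans label (informative).
#' @param planted_cpg_snps data.frame (`snp`, `cpg`) of SNPs to co-locate with
#'   a CpG (distance 0); these receive a strong direct effect `cpg_snp_beta`.
#' @param planted_eqtls data.frame (`snp`, `transcript`, `beta`).
#' @param mediation_triples data.frame (`snp`, `cpg`, `trait`, `model`,
#'   `beta_gm`, `beta_mp`, `beta_gp`); `model` is `"causal"`, `"independent"`
#'   or `"reactive"`. For causal and independent triples the G->M arm must
#'   also appear in `planted_mqtls` (checked by [simulate_cohort()]).
#' @param noise_sd list of residual SDs per layer: `methylation`,
#'   `expression`, `phenotype` (all > 0).
#' @param batch_labels batch label set; samples are assigned at random.
#' @param batch_shift named per-batch additive shift applied to methylation
#'   and expression.
#' @param covariate_effects list with scalars `age` and `bmi`: per-unit
#'   covariate effect added to every CpG M-value (confounding structure).
#' @param cpg_snp_beta per-allele effect of a planted CpG-SNP on its CpG.
#' @param cohort_labels sub-cohort label set.
#' @param seed master RNG seed (integer < 2^31 - 10).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200, n_snps = 5000, n_cpgs = 2000,
                              n_transcripts = 500, ld_block_size = 10,
                              within_block_r = 0.8,
                              maf_range = c(0.1, 0.5),
                              planted_mqtls = NULL,
                              planted_cpg_snps = NULL,
                              planted_eqtls = NULL,
                              mediation_triples = NULL,
                              noise_sd = list(methylation = 0.5,
                                              expression = 0.5,
                                              phenotype = 0.5),
                              batch_labels = c("batch1", "batch2"),
                              batch_shift = c(batch1 = 0, batch2 = 0.4),
                              covariate_effects = list(age = 0.01, bmi = 0.02),
                              cpg_snp_beta = -2,
                              cohort_labels = c("cohort1", "cohort2"),
                              seed = 20160620) {
  stopifnot(n_samples >= 2, n_snps >= 1, n_cpgs >= 1, n_transcripts >= 0,
            ld_block_size >= 1)
  if (within_block_r < 0 || within_block_r >= 1) {
    stop("within_block_r must lie in [0, 1)")
  }
  if (maf_range[1] <= 0.05 - 1e-12 || maf_range[2] > 0.5 || diff(maf_range) < 0) {
    stop("maf_range must be an interval within (0.05, 0.5]")
  }
  if (any(unlist(noise_sd) <= 0)) stop("noise_sd must be > 0 in every layer")
  if (seed >= 2^31 - 10) stop("seed too large")
  cfg <- structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_cpgs = as.integer(n_cpgs), n_transcripts = as.integer(n_transcripts),
    ld_block_size = as.integer(ld_block_size),
    within_block_r = within_block_r, maf_range = maf_range,
    planted_mqtls = planted_mqtls, planted_cpg_snps = planted_cpg_snps,
    planted_eqtls = planted_eqtls, mediation_triples = mediation_triples,
    noise_sd = noise_sd, batch_labels = batch_labels,
    batch_shift = batch_shift, covariate_effects = covariate_effects,
    cpg_snp_beta = cpg_snp_beta, cohort_labels = cohort_labels,
    seed = as.integer(seed)), class = "simulation_config")
  check_indices <- function(idx, n, what) {
    if (length(idx) && (any(idx < 1) || any(idx > n))) {
      stop("planted ", what, " index out of range")
    }
  }
  pm <- cfg$planted_mqtls
  if (!is.null(pm)) {
    check_indices(pm$snp, n_snps, "SNP"); check_indices(pm$cpg, n_cpgs, "CpG")
  }
  pc <- cfg$planted_cpg_snps
  if (!is.null(pc)) {
    check_indices(pc$snp, n_snps, "SNP"); check_indices(pc$cpg, n_cpgs, "CpG")
  }
  pe <- cfg$planted_eqtls
  if (!is.null(pe)) {
    check_indices(pe$snp, n_snps, "SNP")
    check_indices(pe$transcript, n_transcripts, "transcript")
  }
  mt <- cfg$mediation_triples
  if (!is.null(mt)) {
    check_indices(mt$snp, n_snps, "SNP"); check_indices(mt$cpg, n_cpgs, "CpG")
    bad <- setdiff(mt$model, c("causal", "independent", "reactive"))
    if (length(bad)) stop("unknown mediation model label(s): ",
                          paste(bad, collapse = ", "))
    if (!all(mt$trait %in% trait_registry()$trait)) {
      stop("mediation trait not in registry")
    }
  }
  cfg
}

# Deterministic genome layout: features are laid on the 22 autosomes in
# contiguous runs with fixed spacing, so cis/trans structure is controlled by
# the index arithmetic alone (no randomness).
snp_layout <- function(config) {
  n <- config$n_snps
  per <- ceiling(n / N_SIM_CHROMS)
  i <- seq_len(n) - 1L
  chrom <- as.character(i %/% per + 1L)
  within <- i %% per
  data.frame(snp_id = sprintf("snp%05d", seq_len(n)), chrom = chrom,
             pos = POS_OFFSET + within * SNP_SPACING,
             stringsAsFactors = FALSE)
}

cpg_layout <- function(config) {
  n <- config$n_cpgs
  per <- ceiling(n / N_SIM_CHROMS)
  snp_per <- ceiling(config$n_snps / N_SIM_CHROMS)
  span <- snp_per * SNP_SPACING
  spacing <- max(100L, as.integer(floor(span / per / 100) * 100))
  i <- seq_len(n) - 1L
  chrom <- as.character(i %/% per + 1L)
  within <- i %% per
  data.frame(cpg_id = sprintf("cg%07d", seq_len(n)), chrom = chrom,
             pos = POS_OFFSET + CPG_PHASE + within * spacing,
             stringsAsFactors = FALSE)
}

transcript_layout <- function(config) {
  n <- config$n_transcripts
  if (n == 0) {
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  per <- ceiling(n / N_SIM_CHROMS)
  snp_per <- ceiling(config$n_snps / N_SIM_CHROMS)
  span <- snp_per * SNP_SPACING
  spacing <- max(1000L, as.integer(floor(span / per / 100) * 100))
  i <- seq_len(n) - 1L
  chrom <- as.character(i %/% per + 1L)
  within <- i %% per
  start <- POS_OFFSET + 29L + within * spacing
  data.frame(transcript_id = sprintf("tx%05d", seq_len(n)), chrom = chrom,
             start = start, end = start + 5000L,
             gene = sprintf("GENE%05d", seq_len(n)), stringsAsFactors = FALSE)
}

#' Simulate LD-block genotype dosages
#'
#' Within each block a shared latent biallelic variant is drawn per haplotype
#' at the block's MAF; each SNP copies the latent haplotype allele with
#' probability `sqrt(within_block_r)` and otherwise redraws a fresh allele at
#' the same frequency. This makes the dosage correlation between any two SNPs
#' of a block equal `within_block_r` in expectation, leaves Hardy-Weinberg
#' equilibrium intact marginally (haplotypes are independent), and gives r²
#' ≈ `within_block_r`² between adjacent SNPs. Blocks are mutually independent.
#'
#' @param config a [simulation_config()].
#' @return A [genotype_matrix()] with deterministic positions (fixed spacing
#'   on 22 chromosomes) and per-block MAFs drawn from `maf_range`.
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  lay <- snp_layout(config)
  n <- config$n_samples
  copy_p <- sqrt(config$within_block_r)
  dosage <- matrix(NA_real_, n, config$n_snps)
  maf <- numeric(config$n_snps)
  # blocks restart at chromosome boundaries
  per <- ceiling(config$n_snps / N_SIM_CHROMS)
  idx <- seq_len(config$n_snps) - 1L
  block <- (idx %/% per) * 100000L + (idx %% per) %/% config$ld_block_size
  for (b in unique(block)) {
    cols <- which(block == b)
    p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    h1 <- stats::rbinom(n, 1, p)
    h2 <- stats::rbinom(n, 1, p)
    for (j in cols) {
      a1 <- ifelse(stats::runif(n) < copy_p, h1, stats::rbinom(n, 1, p))
      a2 <- ifelse(stats::runif(n) < copy_p, h2, stats::rbinom(n, 1, p))
      dosage[, j] <- a1 + a2
      maf[j] <- p
    }
  }
  rownames(dosage) <- sprintf("s%04d", seq_len(n))
  ann <- data.frame(snp_id = lay$snp_id, chrom = lay$chrom, pos = lay$pos,
                    ref_allele = "A", alt_allele = "G", maf = maf,
                    stringsAsFactors = FALSE)
  # co-locate declared CpG-SNPs with their CpG (distance 0)
  if (!is.null(config$planted_cpg_snps) && nrow(config$planted_cpg_snps)) {
    cl <- cpg_layout(config)
    for (k in seq_len(nrow(config$planted_cpg_snps))) {
      s <- config$planted_cpg_snps$snp[k]
      g <- config$planted_cpg_snps$cpg[k]
      ann$chrom[s] <- cl$chrom[g]
      ann$pos[s] <- cl$pos[g]
      ann$ref_allele[s] <- "C"
      ann$alt_allele[s] <- "T"
    }
  }
  genotype_matrix(dosage, ann)
}

#' Simulate sample covariates (age, BMI, sub-cohort, batch)
#'
#' Drawn from its own RNG stream (`seed + 1`) so methylation and phenotype
#' layers see identical covariate values.
#'
#' @param config a [simulation_config()].
#' @return data.frame with `sample_id`, `age`, `bmi`, `cohort`, `batch`.
#' @export
simulate_covariates <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_samples
  data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    age = round(stats::runif(n, 40, 80), 1),
    bmi = round(pmin(pmax(stats::rnorm(n, 27.5, 3.5), 18), 45), 1),
    cohort = sample(config$cohort_labels, n, replace = TRUE),
    batch = sample(config$batch_labels, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate CpG methylation (M scale) with planted SNP effects
#'
#' M-values are built as per-CpG baseline + planted additive dosage effects +
#' age/BMI confounding + batch shift + Gaussian noise. A companion intensity
#' pair consistent with each M-value is also emitted (unmethylated channel
#' fixed at 1000, methylated channel back-solved as
#' `round(2^M * (unmeth + 1) - 1)`), so the intensity-to-M transform can be
#' exercised on simulated data.
#'
#' @param genotypes output of [simulate_genotypes()] with the same config.
#' @param config a [simulation_config()].
#' @return list with `methylation` (a [methylation_matrix()], scale `"M"`),
#'   and `intensities` (list of `meth`/`unmeth` matrices).
#' @export
simulate_methylation <- function(genotypes, config) {
  pm <- config$planted_mqtls
  pc <- config$planted_cpg_snps
  if (!is.null(pm) && !is.null(pc)) {
    clash <- interaction(pm$snp, pm$cpg) %in% interaction(pc$snp, pc$cpg)
    if (any(clash)) {
      stop("planted mQTL collides with a CpG-SNP declaration for pair(s): ",
           paste(pm$snp[clash], pm$cpg[clash], sep = "/", collapse = ", "))
    }
  }
  covs <- simulate_covariates(config)
  set.seed(config$seed + 2L)
  n <- config$n_samples
  lay <- cpg_layout(config)
  mu <- stats::rnorm(config$n_cpgs, 0, 2)
  M <- matrix(stats::rnorm(n * config$n_cpgs, 0, config$noise_sd$methylation),
              n, config$n_cpgs)
  M <- sweep(M, 2, mu, "+")
  M <- M + config$covariate_effects$age * (covs$age - mean(covs$age)) +
    config$covariate_effects$bmi * (covs$bmi - mean(covs$bmi))
  M <- M + config$batch_shift[covs$batch]
  if (!is.null(pm)) {
    for (k in seq_len(nrow(pm))) {
      M[, pm$cpg[k]] <- M[, pm$cpg[k]] +
        pm$beta[k] * genotypes$dosage[, pm$snp[k]]
    }
  }
  if (!is.null(pc)) {
    for (k in seq_len(nrow(pc))) {
      M[, pc$cpg[k]] <- M[, pc$cpg[k]] +
        config$cpg_snp_beta * genotypes$dosage[, pc$snp[k]]
    }
  }
  rownames(M) <- rownames(genotypes$dosage)
  ann <- data.frame(cpg_id = lay$cpg_id, chrom = lay$chrom, pos = lay$pos,
                    gene = "", gene_region = sample(GENE_REGIONS,
                                                    config$n_cpgs, TRUE),
                    island_relation = sample(ISLAND_RELATIONS,
                                             config$n_cpgs, TRUE),
                    stringsAsFactors = FALSE)
  unmeth <- matrix(1000, n, config$n_cpgs, dimnames = dimnames(M))
  meth <- round(2^M * (unmeth + 1) - 1)
  list(methylation = methylation_matrix(M, ann, scale = "M"),
       intensities = list(meth = meth, unmeth = unmeth))
}

#' Simulate transcript expression with planted eQTL effects
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param config a [simulation_config()].
#' @return An [expression_matrix()] on a normalized intensity-like scale.
#' @export
simulate_expression <- function(genotypes, config) {
  covs <- simulate_covariates(config)
  set.seed(config$seed + 3L)
  n <- config$n_samples
  lay <- transcript_layout(config)
  mu <- stats::rnorm(config$n_transcripts, 7, 1)
  E <- matrix(stats::rnorm(n * config$n_transcripts, 0,
                           config$noise_sd$expression),
              n, config$n_transcripts)
  E <- sweep(E, 2, mu, "+")
  E <- E + config$batch_shift[covs$batch]
  pe <- config$planted_eqtls
  if (!is.null(pe)) {
    for (k in seq_len(nrow(pe))) {
      E[, pe$transcript[k]] <- E[, pe$transcript[k]] +
        pe$beta[k] * genotypes$dosage[, pe$snp[k]]
    }
  }
  rownames(E) <- rownames(genotypes$dosage)
  expression_matrix(E, lay)
}

trait_baselines <- function() {
  # plausible adult male reference means/SDs; log-scale traits are generated
  # as exp(normal) so they are strictly positive
  data.frame(
    trait = c("fasting_glucose", "fasting_insulin", "homa_b", "homa_ir",
              "hba1c", "cholesterol", "triglycerides", "hdl", "ldl", "whr"),
    mean = c(5.5, log(8), log(100), log(2), 5.6, 5.2, log(1.3), 1.3, 3.4, 0.95),
    sd = c(0.6, 0.5, 0.4, 0.5, 0.4, 0.9, 0.35, 0.3, 0.8, 0.06),
    log_scale = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                  FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate metabolic phenotypes, including mediation triples
#'
#' Traits are drawn around plausible reference values; for each mediation
#' triple the named trait is rebuilt according to the declared model:
#' \describe{
#'   \item{causal}{P = beta_mp * M + noise, where M already carries the
#'     planted beta_gm * G effect (G -> M -> P).}
#'   \item{independent}{P = beta_gp * G + noise with no M -> P path
#'     (G -> P and G -> M separately).}
#'   \item{reactive}{P = beta_gp * G + noise; the CpG is subsequently
#'     overwritten as M = beta_mp * P + noise by
#'     [apply_reactive_triples()] (G -> P -> M).}
#' }
#' Effects on log-scale traits (fasting insulin, HOMA-B, HOMA-IR,
#' triglycerides) are planted on the log scale before exponentiation.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param methylation the [methylation_matrix()] from [simulate_methylation()].
#' @param config a [simulation_config()].
#' @return A [phenotype_table()].
#' @export
simulate_phenotypes <- function(genotypes, methylation, config) {
  covs <- simulate_covariates(config)
  set.seed(config$seed + 4L)
  n <- config$n_samples
  base <- trait_baselines()
  vals <- list()
  mt <- config$mediation_triples
  for (i in seq_len(nrow(base))) {
    tr <- base$trait[i]
    rows <- if (is.null(mt)) integer() else which(mt$trait == tr)
    if (!length(rows)) {
      y <- stats::rnorm(n, base$mean[i], base$sd[i])
    } else {
      y <- base$mean[i] + stats::rnorm(n, 0, config$noise_sd$phenotype)
      for (k in rows) {
        G <- genotypes$dosage[, mt$snp[k]]
        M <- methylation$values[, mt$cpg[k]]
        y <- y + switch(mt$model[k],
          causal = mt$beta_mp[k] * (M - mean(M)),
          independent = mt$beta_gp[k] * G,
          reactive = mt$beta_gp[k] * G)
      }
    }
    vals[[tr]] <- if (base$log_scale[i]) exp(y) else y
  }
  df <- data.frame(sample_id = covs$sample_id, age = covs$age,
                   bmi = covs$bmi, cohort = covs$cohort, batch = covs$batch,
                   stringsAsFactors = FALSE)
  for (tr in names(vals)) df[[tr]] <- vals[[tr]]
  df$whr <- pmax(df$whr, 0.6)
  phenotype_table(df, cohorts = config$cohort_labels)
}

#' Overwrite reactive-triple CpGs as downstream of the phenotype
#'
#' For triples with model `"reactive"` the CpG column is rebuilt as
#' `beta_mp * P + noise`, where P is the trait on its analysis scale
#' (natural log for the log-transformed traits). Uses RNG stream `seed + 7`.
#'
#' @param methylation the [methylation_matrix()] to modify.
#' @param phenotypes the [phenotype_table()] from [simulate_phenotypes()].
#' @param config a [simulation_config()].
#' @return The modified [methylation_matrix()].
#' @export
apply_reactive_triples <- function(methylation, phenotypes, config) {
  mt <- config$mediation_triples
  if (is.null(mt)) return(methylation)
  rows <- which(mt$model == "reactive")
  if (!length(rows)) return(methylation)
  set.seed(config$seed + 7L)
  reg <- trait_registry()
  for (k in rows) {
    P <- phenotypes[[mt$trait[k]]]
    if (reg$log_transform[match(mt$trait[k], reg$trait)]) P <- log(P)
    methylation$values[, mt$cpg[k]] <-
      mt$beta_mp[k] * (P - mean(P)) +
      stats::rnorm(config$n_samples, 0, config$noise_sd$methylation)
  }
  methylation
}

#' Simulate a single (G, M, P) triple for mediation analysis
#'
#' Minimal generator used to study the causal inference test in isolation:
#' one biallelic SNP in Hardy-Weinberg proportions, one CpG, one continuous
#' trait, under one of four generative models.
#'
#' @param n sample size.
#' @param model `"causal"` (G -> M -> P), `"independent"` (G -> P and
#'   G -> M, no M-P edge), `"reactive"` (G -> P -> M), or `"null"` (no
#'   edges at all).
#' @param beta_gm,beta_mp,beta_gp per-unit path coefficients (unused paths
#'   ignored).
#' @param noise_sd residual SD on every generated layer.
#' @param maf minor allele frequency of G.
#' @param seed RNG seed.
#' @return data.frame with columns `G`, `M`, `P`.
#' @export
simulate_triple <- function(n, model = c("causal", "independent", "reactive",
                                         "null"),
                            beta_gm = 1, beta_mp = 1, beta_gp = 1,
                            noise_sd = 0.5, maf = 0.3, seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  G <- stats::rbinom(n, 2, maf)
  e1 <- stats::rnorm(n, 0, noise_sd)
  e2 <- stats::rnorm(n, 0, noise_sd)
  if (model == "causal") {
    M <- beta_gm * G + e1
    P <- beta_mp * M + e2
  } else if (model == "independent") {
    M <- beta_gm * G + e1
    P <- beta_gp * G + e2
  } else if (model == "reactive") {
    P <- beta_gp * G + e2
    M <- beta_mp * P + e1
  } else {
    M <- e1
    P <- e2
  }
  data.frame(G = G, M = M, P = P)
}

#' Simulate external summary statistics and a GWAS-catalog-like table
#'
#' The summary-stats table mimics consortium lookups: SNPs involved in
#' mediation triples get the true total-effect sign at small p; a random
#' filler set gets random signs and uniform p. The catalog table lists a
#' random subset of SNPs with metabolic trait labels at p < 1e-5.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param config a [simulation_config()].
#' @return list with `sumstats` (a [summary_stats_table()]) and `catalog`
#'   (data.frame `snp_id`, `trait`, `p`).
#' @export
simulate_external_tables <- function(genotypes, config) {
  set.seed(config$seed + 5L)
  ann <- genotypes$snps
  mt <- config$mediation_triples
  rows <- list()
  if (!is.null(mt)) {
    for (k in seq_len(nrow(mt))) {
      total <- switch(mt$model[k],
        causal = mt$beta_gm[k] * mt$beta_mp[k],
        independent = mt$beta_gp[k],
        reactive = mt$beta_gp[k])
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = ann$snp_id[mt$snp[k]],
        trait = mt$trait[k],
        effect_allele = ann$alt_allele[mt$snp[k]],
        effect_sign = sign(total),
        p = 1e-4, stringsAsFactors = FALSE)
    }
  }
  filler_n <- min(200L, config$n_snps)
  filler <- sample.int(config$n_snps, filler_n)
  reg <- trait_registry()
  rows[[length(rows) + 1L]] <- data.frame(
    snp_id = ann$snp_id[filler],
    trait = sample(reg$trait, filler_n, replace = TRUE),
    effect_allele = ann$alt_allele[filler],
    effect_sign = sample(c(-1, 1), filler_n, replace = TRUE),
    p = stats::runif(filler_n), stringsAsFactors = FALSE)
  ss <- do.call(rbind, rows)
  ss <- ss[!duplicated(paste(ss$snp_id, ss$trait)), ]
  set.seed(config$seed + 6L)
  cat_n <- min(100L, config$n_snps)
  cat_idx <- sample.int(config$n_snps, cat_n)
  catalog <- data.frame(
    snp_id = ann$snp_id[cat_idx],
    trait = sample(c("BMI", "T2D", "obesity", "triglycerides"), cat_n, TRUE),
    p = 10^-stats::runif(cat_n, 5.1, 20),
    stringsAsFactors = FALSE)
  list(sumstats = summary_stats_table(ss), catalog = catalog)
}

#' Desk-scale default configuration with planted structure
#'
#' 200 samples, 5,000 SNPs, 2,000 CpGs and 500 transcripts with a handful of
#' planted cis and trans mQTLs, CpG-SNPs, eQTLs and one mediation triple per
#' model, positioned via the deterministic genome layout so planted "cis"
#' pairs really are within the 500 kb window.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_simulation_config <- function(...) {
  base <- simulation_config(...)
  # nearest CpG (by layout position) to selected SNPs
  sl <- snp_layout(base); cl <- cpg_layout(base)
  nearest_cpg <- function(snp_idx) {
    same <- which(cl$chrom == sl$chrom[snp_idx])
    same[which.min(abs(cl$pos[same] - sl$pos[snp_idx]))]
  }
  pick_snps <- unique(pmin(base$n_snps,
                           c(25L, round(base$n_snps * c(0.12, 0.3, 0.55, 0.8)))))
  cis <- data.frame(snp = pick_snps,
                    cpg = vapply(pick_snps, nearest_cpg, integer(1)),
                    beta = 1.0, relation = "cis", stringsAsFactors = FALSE)
  # trans: SNP and CpG on different chromosomes
  per_snp <- ceiling(base$n_snps / N_SIM_CHROMS)
  per_cpg <- ceiling(base$n_cpgs / N_SIM_CHROMS)
  trans <- data.frame(snp = c(5L, per_snp + 3L),
                      cpg = c(3L * per_cpg + 2L, 7L * per_cpg + 4L),
                      beta = 0.8, relation = "trans", stringsAsFactors = FALSE)
  trans <- trans[trans$snp <= base$n_snps & trans$cpg <= base$n_cpgs, ]
  cpg_snps <- data.frame(snp = min(base$n_snps, 2L * per_snp + 11L),
                         cpg = min(base$n_cpgs, 2L * per_cpg + 5L))
  eqtls <- NULL
  if (base$n_transcripts > 0) {
    tl <- transcript_layout(base)
    es <- unique(pmin(base$n_snps, c(40L, round(base$n_snps * 0.45))))
    nearest_tx <- function(snp_idx) {
      same <- which(tl$chrom == sl$chrom[snp_idx])
      if (!length(same)) return(NA_integer_)
      same[which.min(abs(tl$start[same] - sl$pos[snp_idx]))]
    }
    eqtls <- data.frame(snp = es,
                        transcript = vapply(es, nearest_tx, integer(1)),
                        beta = 1.2, stringsAsFactors = FALSE)
    eqtls <- eqtls[!is.na(eqtls$transcript), ]
  }
  med_snps <- unique(pmax(1L, pmin(base$n_snps,
                                   round(base$n_snps * c(0.22, 0.5, 0.78)))))
  med <- data.frame(
    snp = med_snps,
    cpg = vapply(med_snps, nearest_cpg, integer(1)),
    trait = c("hba1c", "cholesterol", "whr")[seq_along(med_snps)],
    model = c("causal", "independent", "reactive")[seq_along(med_snps)],
    beta_gm = 1.0, beta_mp = 0.8, beta_gp = 0.8, stringsAsFactors = FALSE)
  # causal/independent triples need their G->M arm planted in methylation
  med_mqtls <- data.frame(snp = med$snp[med$model != "reactive"],
                          cpg = med$cpg[med$model != "reactive"],
                          beta = med$beta_gm[med$model != "reactive"],
                          relation = "cis", stringsAsFactors = FALSE)
  simulation_config(
    n_samples = base$n_samples, n_snps = base$n_snps, n_cpgs = base$n_cpgs,
    n_transcripts = base$n_transcripts, ld_block_size = base$ld_block_size,
    within_block_r = base$within_block_r, maf_range = base$maf_range,
    planted_mqtls = rbind(cis, trans, med_mqtls),
    planted_cpg_snps = cpg_snps, planted_eqtls = eqtls,
    mediation_triples = med, noise_sd = base$noise_sd,
    batch_labels = base$batch_labels, batch_shift = base$batch_shift,
    covariate_effects = base$covariate_effects,
    cpg_snp_beta = base$cpg_snp_beta, cohort_labels = base$cohort_labels,
    seed = base$seed)
}

#' Simulate a full cohort
#'
#' Runs every layer in order (genotypes, covariates, methylation + intensity
#' pairs, expression, phenotypes, reactive overwrites, external tables) and
#' checks that causal/independent mediation triples have their G->M arm
#' planted in the methylation layer.
#'
#' @param config a [simulation_config()].
#' @return list with elements `genotypes`, `covariates`, `methylation`,
#'   `intensities`, `expression`, `phenotypes`, `sumstats`, `catalog`,
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  mt <- config$mediation_triples
  if (!is.null(mt)) {
    need <- mt[mt$model %in% c("causal", "independent"), , drop = FALSE]
    if (nrow(need)) {
      pm <- config$planted_mqtls
      have <- if (is.null(pm)) character() else paste(pm$snp, pm$cpg)
      missing <- !(paste(need$snp, need$cpg) %in% have)
      if (any(missing)) {
        stop("mediation triple(s) without a planted G->M effect: ",
             paste(need$snp[missing], need$cpg[missing], sep = "/",
                   collapse = ", "))
      }
    }
  }
  geno <- simulate_genotypes(config)
  covs <- simulate_covariates(config)
  msim <- simulate_methylation(geno, config)
  expr <- if (config$n_transcripts > 0) simulate_expression(geno, config) else NULL
  pheno <- simulate_phenotypes(geno, msim$methylation, config)
  meth <- apply_reactive_triples(msim$methylation, pheno, config)
  ext <- simulate_external_tables(geno, config)
  list(genotypes = geno, covariates = covs, methylation = meth,
       intensities = msim$intensities, expression = expr, phenotypes = pheno,
       sumstats = ext$sumstats, catalog = ext$catalog, config = config)
}
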