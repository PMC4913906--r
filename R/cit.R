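# Four-condition causal inference test for (G, M, P) triples: methylation M
# mediates the genotype G -> phenotype P association iff
#   1) G and M are associated,
#   2) G and P are associated,
#   3) G is associated with M given P, and
#   4) G is independent of P given M,
# with the omnibus causal p-value the maximum of the four component
# p-values (an intersection-union test). Conditions 1-3 are nested-model F
# tests.
#
# Condition 4 is an equivalence test: rejecting it must mean "G carries no
# information about P beyond M", so the reference distribution is the
# counterfactual in which the entire observed marginal G-P association is
# direct rather than mediated. Surrogate genotypes G* = fitted(G | P, C) +
# permuted residuals preserve the marginal G-P association while severing
# the G-M path; the F statistic for adding G* to P ~ M + C is then large
# whenever a direct effect of the observed strength would survive
# conditioning on M. p4 is the fraction of permuted F* below the observed
# F: near 0 under complete mediation (observed F is null-like, F* is
# large), and roughly uniform when G really does affect P directly.

f_test_nested <- function(y, x_add, X0) {
  qr0 <- qr(X0)
  u <- qr.resid(qr0, y)
  v <- qr.resid(qr0, x_add)
  n <- length(y)
  df <- n - ncol(X0) - 1
  if (df <= 0) stop("nonpositive degrees of freedom in F test")
  ssv <- sum(v^2)
  if (ssv <= 0) return(list(f = 0, p = 1, df = df))
  r <- sum(u * v) / sqrt(sum(u^2) * ssv)
  f <- df * r^2 / max(1 - r^2, .Machine$double.eps)
  list(f = f, p = stats::pf(f, 1, df, lower.tail = FALSE), df = df)
}

#' Component p-values of the causal inference test
#'
#' @param G numeric dosage vector (must be non-constant).
#' @param M numeric methylation vector.
#' @param P numeric phenotype vector.
#' @param covariates optional covariate data.frame (numeric/categorical),
#'   included in every component model.
#' @param B number of permutations for the condition-4 equivalence test
#'   (default 1000; a warning is issued below 100).
#' @param seed RNG seed for the permutations (required; p4 is reproducible
#'   bit-for-bit given `seed` and `B`).
#' @return named numeric vector `p1` (G~M), `p2` (G~P), `p3` (G~M|P),
#'   `p4` (equivalence test of G independent of P given M: the fraction of
#'   direct-effect surrogate F statistics below the observed conditional F).
#' @export
cit_components <- function(G, M, P, covariates = NULL, B = 1000, seed) {
  if (missing(seed)) stop("seed is required for the permutation test")
  if (B < 100) warning("B < 100 permutations gives a coarse p4")
  n0 <- length(G)
  C <- covariate_design(covariates, n0)
  ok <- !is.na(G) & !is.na(M) & !is.na(P) &
    (ncol(C) == 0 | stats::complete.cases(C))
  G <- G[ok]; M <- M[ok]; P <- P[ok]
  C <- C[ok, , drop = FALSE]
  n <- length(G)
  if (n < 30) warning("n < 30: CIT component tests are unreliable")
  if (stats::var(G) == 0) stop("constant genotype vector")
  one <- rep(1, n)
  X_c <- cbind(one, C)
  p1 <- f_test_nested(M, G, X_c)$p
  p2 <- f_test_nested(P, G, X_c)$p
  p3 <- f_test_nested(M, G, cbind(X_c, P))$p
  # condition 4: equivalence test. Observed F for adding G to P ~ M + C is
  # compared against F* computed from surrogate genotypes that keep the
  # marginal G-P association but are independent of M given P.
  X0 <- cbind(X_c, M)
  qr0 <- qr(X0)
  u <- qr.resid(qr0, P)
  v_obs <- qr.resid(qr0, G)
  df <- n - ncol(X0) - 1
  f_from_r2 <- function(r2) df * r2 / pmax(1 - r2, .Machine$double.eps)
  ssu <- sum(u^2)
  f_obs <- f_from_r2(sum(u * v_obs)^2 / (ssu * sum(v_obs^2)))
  qr_p <- qr(cbind(X_c, P))
  e <- qr.resid(qr_p, G)
  g_fit <- G - e
  set.seed(seed)
  E <- vapply(seq_len(B), function(b) e[sample.int(n)], numeric(n))
  V <- qr.resid(qr0, E) + qr.resid(qr0, g_fit)
  cross <- colSums(V * u)
  ss <- colSums(V^2)
  r2_star <- ifelse(ss > 0, cross^2 / (ssu * ss), 0)
  f_star <- f_from_r2(r2_star)
  p4 <- mean(f_star < f_obs)
  c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

#' Omnibus causal p-value
#'
#' Intersection-union combination of the four component tests: the omnibus
#' p-value is their maximum, so causality is supported only when every
#' condition holds.
#'
#' @param p1,p2,p3,p4 component p-values in \[0, 1\] (alternatively pass a
#'   single vector of four as `p1`).
#' @return `max(p1, p2, p3, p4)`.
#' @export
cit_omnibus <- function(p1, p2, p3, p4) {
  p <- if (missing(p2)) p1 else c(p1, p2, p3, p4)
  stopifnot(length(p) == 4, all(p >= 0 & p <= 1))
  max(p)
}

#' Classify a (G, M, P) triple as causal, reactive, independent or ambiguous
#'
#' Runs the omnibus test in both directions: forward (M mediates G -> P)
#' and reverse (P mediates G -> M, i.e. the roles of M and P swapped).
#' Classification: `causal` if forward p < `alpha` and reverse >= `alpha`;
#' `reactive` if reverse p < `alpha` and forward >= `alpha`; `ambiguous` if
#' both; `independent` otherwise. No multiple-testing correction is applied
#' to the omnibus p-values.
#'
#' @param G,M,P aligned numeric vectors.
#' @param covariates optional covariate data.frame.
#' @param alpha decision level (default 0.05).
#' @param B permutations for the equivalence components (default 1000).
#' @param seed RNG seed (forward uses `seed`, reverse `seed + 1`).
#' @param snp_id,cpg_id,trait optional identifiers carried into the record.
#' @return one-row data.frame: identifiers, forward `p1..p4`, `p_causal`,
#'   reverse `p_reverse`, `classification`, `n_used`, `n_permutations`,
#'   `seed`.
#' @export
classify_relationship <- function(G, M, P, covariates = NULL, alpha = 0.05,
                                  B = 1000, seed,
                                  snp_id = NA_character_,
                                  cpg_id = NA_character_,
                                  trait = NA_character_) {
  if (missing(seed)) stop("seed is required")
  fwd <- cit_components(G, M, P, covariates, B = B, seed = seed)
  rev <- cit_components(G, P, M, covariates, B = B, seed = seed + 1L)
  p_causal <- cit_omnibus(fwd)
  p_reverse <- cit_omnibus(rev)
  classification <- if (p_causal < alpha && p_reverse >= alpha) {
    "causal"
  } else if (p_reverse < alpha && p_causal >= alpha) {
    "reactive"
  } else if (p_causal < alpha && p_reverse < alpha) {
    "ambiguous"
  } else {
    "independent"
  }
  n_used <- sum(!is.na(G) & !is.na(M) & !is.na(P))
  data.frame(snp_id = snp_id, cpg_id = cpg_id, trait = trait,
             p1 = unname(fwd["p1"]), p2 = unname(fwd["p2"]),
             p3 = unname(fwd["p3"]), p4 = unname(fwd["p4"]),
             p_causal = p_causal, p_reverse = p_reverse,
             classification = classification, n_used = n_used,
             n_permutations = B, seed = seed, stringsAsFactors = FALSE)
}

#' Run the causal inference test over a list of triples
#'
#' Convenience wrapper mapping (snp_id, cpg_id, trait) rows onto the cohort
#' matrices and calling [classify_relationship()] for each, with the
#' covariate rule of the phenotype association models (age + sub-cohort,
#' plus BMI for the glycaemic traits).
#'
#' @param triples data.frame with `snp_id`, `cpg_id`, `trait`.
#' @param genotypes a [genotype_matrix()].
#' @param methylation a [methylation_matrix()].
#' @param phenotypes a [phenotype_table()] (trait-transformed; see
#'   [transform_traits()]).
#' @param alpha,B as in [classify_relationship()].
#' @param seed base seed; triple i uses `seed + 2 * (i - 1)`.
#' @return data.frame with one record per triple.
#' @export
cit_test <- function(triples, genotypes, methylation, phenotypes,
                     alpha = 0.05, B = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  reg <- trait_registry()
  idx <- match(phenotypes$sample_id, rownames(genotypes$dosage))
  if (anyNA(idx)) stop("phenotype samples missing from genotypes")
  midx <- match(phenotypes$sample_id, rownames(methylation$values))
  if (anyNA(midx)) stop("phenotype samples missing from methylation")
  out <- vector("list", nrow(triples))
  for (i in seq_len(nrow(triples))) {
    tr <- triples$trait[i]
    row <- match(tr, reg$trait)
    if (is.na(row)) stop("trait not in registry: ", tr)
    covs <- data.frame(age = phenotypes$age, cohort = phenotypes$cohort,
                       stringsAsFactors = FALSE)
    if (reg$bmi_covariate[row]) covs$bmi <- phenotypes$bmi
    out[[i]] <- classify_relationship(
      G = genotypes$dosage[idx, triples$snp_id[i]],
      M = methylation$values[midx, triples$cpg_id[i]],
      P = phenotypes[[tr]],
      covariates = covs, alpha = alpha, B = B,
      seed = seed + 2L * (i - 1L),
      snp_id = triples$snp_id[i], cpg_id = triples$cpg_id[i], trait = tr)
  }
  do.call(rbind, out)
}
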