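# cis/trans association scans. The per-pair reference model is ordinary
# least squares of the response on [intercept, dosage, covariates]; the fast
# scan residualizes both sides against [intercept, covariates] and converts
# per-pair residual correlations to t statistics (Frisch-Waugh-Lovell), so
# the two routes agree to numerical precision for any covariate set.

#' Pair bookkeeping container
#'
#' Records how a SNP x feature cross partitions into cis and trans pairs.
#' Counts are kept as doubles because genome-wide products (hundreds of
#' billions of pairs) exceed integer range; they remain exact below 2^53.
#'
#' @param n_snps,n_features marginal counts.
#' @param n_cis number of cis pairs.
#' @param window cis window in bp.
#' @return An object of class `pair_classification` with `n_total_pairs`,
#'   `n_cis_pairs`, `n_trans_pairs`, `window`.
#' @export
pair_classification <- function(n_snps, n_features, n_cis, window = 500000) {
  n_total <- as.numeric(n_snps) * as.numeric(n_features)
  n_cis <- as.numeric(n_cis)
  if (n_cis < 0 || n_cis > n_total) stop("n_cis outside [0, n_total]")
  structure(list(n_snps = as.numeric(n_snps),
                 n_features = as.numeric(n_features),
                 n_total_pairs = n_total, n_cis_pairs = n_cis,
                 n_trans_pairs = n_total - n_cis, window = window),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("pairs: %.0f total = %.0f cis + %.0f trans (window %d bp)\n",
              x$n_total_pairs, x$n_cis_pairs, x$n_trans_pairs,
              as.integer(x$window)))
  invisible(x)
}

#' Classify SNP-feature pairs as cis or trans
#'
#' A pair is cis iff SNP and feature lie on the same chromosome and
#' |pos_snp - pos_feature| <= `window` (boundary inclusive); every other
#' pair, including same-chromosome pairs beyond the window, is trans.
#'
#' @param snp_ann SNP annotation with `snp_id`, `chrom`, `pos`.
#' @param feature_ann feature annotation with an id column (`cpg_id` or
#'   `transcript_id`), `chrom`, and either `pos` or `start`/`end` (for a
#'   span, distance is measured to the nearest span end; 0 inside the span).
#' @param window cis window in bp (default 500 kb).
#' @return list with `classification` (a [pair_classification()]) and
#'   `cis_pairs` (data.frame `snp_id`, `feature_id`, `distance`).
#' @export
classify_pairs <- function(snp_ann, feature_ann, window = 500000) {
  id_col <- intersect(c("cpg_id", "transcript_id", "feature_id"),
                      names(feature_ann))[1]
  if (is.na(id_col)) stop("feature annotation lacks an id column")
  if (!"chrom" %in% names(feature_ann) ||
      anyNA(feature_ann$chrom)) stop("unannotated feature (missing chrom)")
  if ("pos" %in% names(feature_ann)) {
    fstart <- feature_ann$pos; fend <- feature_ann$pos
  } else if (all(c("start", "end") %in% names(feature_ann))) {
    fstart <- feature_ann$start; fend <- feature_ann$end
  } else {
    stop("feature annotation lacks pos or start/end")
  }
  if (anyNA(fstart) || anyNA(fend)) stop("unannotated feature (missing position)")
  out <- vector("list", 0L)
  for (ch in unique(snp_ann$chrom)) {
    si <- which(snp_ann$chrom == ch)
    fi <- which(feature_ann$chrom == ch)
    if (!length(si) || !length(fi)) next
    # features sorted by start; for each SNP take the window slice
    o <- order(fstart[fi])
    fi <- fi[o]
    fs <- fstart[fi]; fe <- fend[fi]
    max_span <- max(fe - fs)
    for (s in si) {
      pos <- snp_ann$pos[s]
      # candidate slice on the start-sorted features; max_span widens the
      # left edge so long spans ending near the SNP are not missed
      lo <- findInterval(pos - window - max_span, fs)
      hi <- findInterval(pos + window, fs)
      if (hi < 1) next
      cand <- seq.int(max(1L, lo), hi)
      d <- pmax(0, pmax(fs[cand] - pos, pos - fe[cand]))
      keep <- d <= window
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          snp_id = snp_ann$snp_id[s],
          feature_id = feature_ann[[id_col]][fi[cand[keep]]],
          distance = d[keep], stringsAsFactors = FALSE)
      }
    }
  }
  cis_pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(), feature_id = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  list(classification = pair_classification(nrow(snp_ann), nrow(feature_ann),
                                            nrow(cis_pairs), window),
       cis_pairs = cis_pairs)
}

# reference-coded design matrix for the covariates: numeric columns pass
# through, character/factor columns expand to indicator columns
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) return(NULL)
      m <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1])
    }
    m
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (!length(cols)) return(matrix(numeric(0), nrow = n, ncol = 0))
  do.call(cbind, cols)
}

#' Per-pair QTL regression
#'
#' Ordinary least squares of `response` on \[intercept, dosage, covariates\]
#' with a two-sided t test on the dosage coefficient, df = n_used - k - 2
#' (k = covariate columns after categorical expansion). Missing dosages are
#' mean-imputed; samples with missing response or covariates are dropped.
#'
#' @param response numeric response vector (CpG M-values, expression, ...).
#' @param dosage numeric 0/1/2/NA dosage vector.
#' @param covariates optional data.frame of covariates (numeric or
#'   categorical).
#' @return list with `beta`, `se`, `t_stat`, `p`, `n_used`, `flag`
#'   (`"ok"` or `"zero_variance"`, the latter with NA statistics).
#' @export
fit_qtl <- function(response, dosage, covariates = NULL) {
  n <- length(response)
  C <- covariate_design(covariates, n)
  complete <- !is.na(response) & (ncol(C) == 0 | stats::complete.cases(C))
  y <- response[complete]
  g <- dosage[complete]
  C <- C[complete, , drop = FALSE]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  n_used <- length(y)
  k <- ncol(C)
  if (n_used < k + 3) stop("too few complete observations (", n_used, ")")
  if (stats::var(g) == 0 || !is.finite(stats::var(g))) {
    return(list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                p = NA_real_, n_used = n_used, flag = "zero_variance"))
  }
  X <- cbind(intercept = 1, dosage = g, C)
  fit <- stats::lm.fit(X, y)
  df <- n_used - k - 2
  if (df <= 0) stop("nonpositive residual degrees of freedom")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["dosage"])
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(beta = beta, se = se, t_stat = t_stat, p = p, n_used = n_used,
       flag = "ok")
}

# residualize the columns of Y against [1, C]; returns the residual matrix
residualize <- function(Y, C) {
  X <- cbind(rep(1, nrow(Y)), C)
  qr_x <- qr(X)
  qr.resid(qr_x, Y)
}

#' Fast matrix association scan over SNP-feature pairs
#'
#' Residualizes both the response columns and the (mean-imputed) predictor
#' columns against \[intercept, covariates\], computes per-pair correlations
#' of residuals, and converts them to t statistics with df = n - k - 2. By
#' the Frisch-Waugh-Lovell theorem the resulting beta/se/t/p equal the
#' per-pair [fit_qtl()] results.
#'
#' @param predictors numeric matrix, samples x predictors (dosages, or
#'   methylation for methylation-expression scans); NAs mean-imputed
#'   per column.
#' @param responses numeric matrix, samples x features; must be complete.
#' @param covariates optional covariate data.frame (numeric/categorical).
#' @param pairs either `NULL` (all predictor x response pairs) or a
#'   data.frame with `snp_id`/`feature_id` (and optionally `distance`,
#'   `relation`) naming columns of the two matrices.
#' @param p_keep retain only records with p <= this (default 1, keep all);
#'   mirrors the output threshold of genome-wide scan tools.
#' @return data.frame of records: `snp_id`, `feature_id`, `beta`, `se`,
#'   `t_stat`, `p`, `n_used` (+ any extra `pairs` columns carried through).
#' @export
scan_pairs <- function(predictors, responses, covariates = NULL, pairs = NULL,
                       p_keep = 1) {
  predictors <- as.matrix(predictors)
  responses <- as.matrix(responses)
  n <- nrow(predictors)
  if (nrow(responses) != n) stop("sample dimension mismatch")
  if (anyNA(responses)) stop("responses must be complete")
  C <- covariate_design(covariates, n)
  if (ncol(C) && anyNA(C)) stop("covariates must be complete for the matrix scan")
  k <- ncol(C)
  df <- n - k - 2
  if (df <= 0) stop("nonpositive residual degrees of freedom")
  # mean-impute predictor NAs per column
  if (anyNA(predictors)) {
    mu <- colMeans(predictors, na.rm = TRUE)
    idx <- which(is.na(predictors), arr.ind = TRUE)
    predictors[idx] <- mu[idx[, 2]]
  }
  RG <- residualize(predictors, C)
  RY <- residualize(responses, C)
  ss_g <- colSums(RG^2)
  ss_y <- colSums(RY^2)
  if (is.null(pairs)) {
    pairs <- expand.grid(snp_id = colnames(predictors),
                         feature_id = colnames(responses),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  gi <- match(pairs$snp_id, colnames(predictors))
  fi <- match(pairs$feature_id, colnames(responses))
  if (anyNA(gi) || anyNA(fi)) stop("pair refers to unknown predictor/feature id")
  cross <- colSums(RG[, gi, drop = FALSE] * RY[, fi, drop = FALSE])
  denom <- ss_g[gi] * ss_y[fi]
  r <- ifelse(denom > 0, cross / sqrt(denom), NA_real_)
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  beta <- ifelse(ss_g[gi] > 0, cross / ss_g[gi], NA_real_)
  se <- ifelse(abs(t_stat) > 0, beta / t_stat,
               sqrt(ss_y[fi] / df / ss_g[gi]))
  p <- 2 * stats::pt(-abs(t_stat), df)
  out <- data.frame(pairs, beta = beta, se = se, t_stat = t_stat, p = p,
                    n_used = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (p_keep < 1) out <- out[!is.na(out$p) & out$p <= p_keep, , drop = FALSE]
  out
}

# full predictor x response cross in SNP chunks, keeping only records with
# p <= p_keep; avoids materializing hundreds of millions of pair ids
scan_cross <- function(predictors, responses, covariates = NULL,
                       p_keep = 1, chunk = 512L) {
  predictors <- as.matrix(predictors)
  responses <- as.matrix(responses)
  n <- nrow(predictors)
  if (anyNA(responses)) stop("responses must be complete")
  C <- covariate_design(covariates, n)
  k <- ncol(C)
  df <- n - k - 2
  if (df <= 0) stop("nonpositive residual degrees of freedom")
  if (anyNA(predictors)) {
    mu <- colMeans(predictors, na.rm = TRUE)
    idx <- which(is.na(predictors), arr.ind = TRUE)
    predictors[idx] <- mu[idx[, 2]]
  }
  RG <- residualize(predictors, C)
  RY <- residualize(responses, C)
  ss_g <- colSums(RG^2)
  ss_y <- colSums(RY^2)
  sg <- sqrt(ss_g); sg[sg == 0] <- Inf  # zero-variance SNPs yield r = 0
  sy <- sqrt(ss_y); sy[sy == 0] <- Inf
  Gn <- sweep(RG, 2, sg, "/")
  Yn <- sweep(RY, 2, sy, "/")
  out <- vector("list", 0L)
  starts <- seq(1L, ncol(Gn), by = chunk)
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, ncol(Gn))
    r <- crossprod(Gn[, cols, drop = FALSE], Yn)
    r <- pmin(pmax(r, -1), 1)
    t_stat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(t_stat), df)
    keep <- which(p <= p_keep, arr.ind = TRUE)
    if (!nrow(keep)) next
    gi <- cols[keep[, 1]]
    fi <- keep[, 2]
    rr <- r[keep]
    beta <- rr * sy[fi] / sg[gi]  # = cross / ss_g
    tt <- t_stat[keep]
    se <- ifelse(abs(tt) > 0, beta / tt, sqrt(ss_y[fi] / df / ss_g[gi]))
    out[[length(out) + 1L]] <- data.frame(
      snp_id = colnames(predictors)[gi],
      feature_id = colnames(responses)[fi],
      beta = beta, se = se, t_stat = tt, p = p[keep], n_used = n,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(snp_id = character(), feature_id = character(),
                      beta = numeric(), se = numeric(), t_stat = numeric(),
                      p = numeric(), n_used = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan genotypes against a response matrix in cis or trans
#'
#' Builds the pair index from [classify_pairs()] and runs [scan_pairs()].
#' For `relation = "cis"` only same-chromosome pairs within the window are
#' tested and records carry their distance; for `"trans"` all remaining
#' pairs are tested (distance undefined across chromosomes).
#'
#' @param genotypes a [genotype_matrix()].
#' @param responses a [methylation_matrix()], [expression_matrix()], or
#'   plain samples x features matrix with an annotation supplied via
#'   `feature_ann`.
#' @param covariates covariate data.frame aligned to samples.
#' @param relation `"cis"` or `"trans"`.
#' @param window cis window in bp.
#' @param p_keep output p-value threshold (see [scan_pairs()]).
#' @param feature_ann feature annotation when `responses` is a bare matrix.
#' @return data.frame of QTL records with `relation` and `distance` columns.
#' @export
scan_qtl <- function(genotypes, responses, covariates = NULL,
                     relation = c("cis", "trans"), window = 500000,
                     p_keep = 1, feature_ann = NULL) {
  relation <- match.arg(relation)
  if (inherits(responses, "methylation_matrix")) {
    feature_ann <- responses$cpgs; Y <- responses$values
  } else if (inherits(responses, "expression_matrix")) {
    feature_ann <- responses$transcripts; Y <- responses$values
  } else {
    if (is.null(feature_ann)) stop("feature_ann required for a bare matrix")
    Y <- as.matrix(responses)
  }
  cls <- classify_pairs(genotypes$snps, feature_ann, window = window)
  if (relation == "cis") {
    pairs <- cls$cis_pairs
    if (!nrow(pairs)) {
      return(data.frame(snp_id = character(), feature_id = character(),
                        distance = numeric(), beta = numeric(),
                        se = numeric(), t_stat = numeric(), p = numeric(),
                        n_used = integer(), relation = character(),
                        stringsAsFactors = FALSE))
    }
  } else {
    id_col <- intersect(c("cpg_id", "transcript_id", "feature_id"),
                        names(feature_ann))[1]
    cis_key <- paste(cls$cis_pairs$snp_id, cls$cis_pairs$feature_id)
    rec <- scan_cross(genotypes$dosage, Y, covariates, p_keep = p_keep)
    rec <- rec[!(paste(rec$snp_id, rec$feature_id) %in% cis_key), ,
               drop = FALSE]
    rec$distance <- rep(NA_real_, nrow(rec))
    rec$relation <- rep(relation, nrow(rec))
    rec <- rec[c("snp_id", "feature_id", "distance", "beta", "se",
                 "t_stat", "p", "n_used", "relation")]
    rownames(rec) <- NULL
    return(rec)
  }
  rec <- scan_pairs(genotypes$dosage, Y, covariates, pairs, p_keep = p_keep)
  rec$relation <- relation
  rec
}

#' Detect CpG-SNPs
#'
#' Returns SNP-CpG pairs on the same chromosome whose positions differ by 0
#' or 1 bp -- SNPs sitting in the C or G of the interrogated dinucleotide,
#' which can create or destroy the methylatable site.
#'
#' @param snp_ann SNP annotation (`snp_id`, `chrom`, `pos`).
#' @param cpg_ann CpG annotation (`cpg_id`, `chrom`, `pos`).
#' @return data.frame with `snp_id`, `cpg_id`, `distance` (0 or 1).
#' @export
detect_cpg_snps <- function(snp_ann, cpg_ann) {
  out <- vector("list", 0L)
  for (ch in intersect(unique(snp_ann$chrom), unique(cpg_ann$chrom))) {
    si <- which(snp_ann$chrom == ch)
    ci <- which(cpg_ann$chrom == ch)
    cp <- cpg_ann$pos[ci]
    o <- order(cp)
    ci <- ci[o]; cp <- cp[o]
    for (s in si) {
      j <- findInterval(snp_ann$pos[s] + 1, cp)
      cand <- j + c(-1L, 0L, 1L)
      cand <- cand[cand >= 1 & cand <= length(cp)]
      hit <- cand[abs(cp[cand] - snp_ann$pos[s]) <= 1]
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          snp_id = snp_ann$snp_id[s], cpg_id = cpg_ann$cpg_id[ci[hit]],
          distance = abs(cp[hit] - snp_ann$pos[s]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(snp_id = character(), cpg_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Methylation-expression association scan
#'
#' Regresses transcript expression on CpG methylation (with covariates) for
#' CpGs falling in an asymmetric window around the gene span: `upstream` bp
#' before the span start through `downstream` bp after the span end,
#' computed on the genomic plus strand (strand is ignored). Benjamini-
#' Hochberg q-values are attached across all tested pairs; the significant
#' set is q < `fdr`.
#'
#' @param methylation a [methylation_matrix()] (predictor).
#' @param expression an [expression_matrix()] (response). Transcripts
#'   without coordinates are skipped with a warning.
#' @param covariates covariate data.frame.
#' @param upstream,downstream window in bp (defaults 500 kb / 100 kb).
#' @param fdr significance level on the q-value (default 0.05).
#' @return data.frame of records with `q` and `significant` columns.
#' @export
scan_methylation_expression <- function(methylation, expression,
                                        covariates = NULL,
                                        upstream = 500000, downstream = 100000,
                                        fdr = 0.05) {
  tx <- expression$transcripts
  bad <- is.na(tx$chrom) | is.na(tx$start) | is.na(tx$end)
  if (any(bad)) {
    warning(sum(bad), " transcript(s) without coordinates skipped")
    tx <- tx[!bad, , drop = FALSE]
  }
  cpgs <- methylation$cpgs
  out <- vector("list", 0L)
  for (ch in intersect(unique(tx$chrom), unique(cpgs$chrom))) {
    ti <- which(tx$chrom == ch)
    ci <- which(cpgs$chrom == ch)
    for (t in ti) {
      lo <- tx$start[t] - upstream
      hi <- tx$end[t] + downstream
      hit <- ci[cpgs$pos[ci] >= lo & cpgs$pos[ci] <= hi]
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          snp_id = cpgs$cpg_id[hit], feature_id = tx$transcript_id[t],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cpg_id = character(), transcript_id = character(),
                      beta = numeric(), se = numeric(), t_stat = numeric(),
                      p = numeric(), q = numeric(), n_used = integer(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, out)
  rec <- scan_pairs(methylation$values, expression$values, covariates, pairs)
  names(rec)[names(rec) == "snp_id"] <- "cpg_id"
  names(rec)[names(rec) == "feature_id"] <- "transcript_id"
  rec$q <- stats::p.adjust(rec$p, method = "BH")
  rec$significant <- rec$q < fdr
  rec
}
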