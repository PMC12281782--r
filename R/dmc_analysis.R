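# Patient-aware differential methylation and expression testing.
#
# Outcomes (recurrence, metastasis) are patient-level labels while the data
# carry several samples per patient, so ordinary per-CpG group tests would
# treat correlated samples as independent. The test implemented here is the
# array-world approximation of a random-intercept model: a single consensus
# within-patient correlation is estimated by pooling per-feature
# compound-symmetry (intraclass) correlation estimates on a
# variance-stabilized scale, and each feature is then tested by generalized
# least squares with block compound-symmetry covariance and a Wald test on
# the group coefficient.

clamp_logit <- function(beta, eps = 1e-3) {
  stats::qlogis(pmin(pmax(beta, eps), 1 - eps))
}

# pooled intraclass correlation of Y's columns grouped by `patient`, after
# removing per-group means; Fisher-z pooling across features
estimate_consensus_correlation <- function(Y, patient, group) {
  pat <- factor(patient)
  grp <- factor(group)
  n <- ncol(Y)
  a <- nlevels(pat)
  if (a >= n) return(0)                       # one sample per patient
  # residuals after group means
  gm <- t(rowsum(t(Y), grp) / as.vector(table(grp)))
  R <- Y - gm[, as.integer(grp), drop = FALSE]
  ni <- as.vector(table(pat))
  pm <- t(rowsum(t(R), pat)) / rep(ni, each = nrow(Y))
  SSW <- rowSums((R - pm[, as.integer(pat), drop = FALSE])^2)
  SSB <- rowSums(sweep(pm^2, 2, ni, "*")) -
    rowSums(R)^2 / n
  df_w <- n - a
  df_b <- a - nlevels(grp)
  if (df_w <= 0 || df_b <= 0) return(0)
  k0 <- (n - sum(ni^2) / n) / (a - 1)
  msw <- SSW / df_w
  msb <- SSB / df_b
  sb2 <- (msb - msw) / k0
  rho <- sb2 / (sb2 + msw)
  rho <- rho[is.finite(rho)]
  if (!length(rho)) return(0)
  # a compound-symmetry block of size k needs rho > -1/(k - 1)
  lo <- -0.9 / max(max(ni) - 1, 1)
  rho <- pmin(pmax(rho, lo), 0.99)
  min(max(tanh(mean(atanh(rho))), lo), 0.99)
}

# whitening constants of a compound-symmetry block of size k:
# ystar = c1 * (y - ybar) + c2 * ybar
cs_whiten_consts <- function(k, rho) {
  list(c1 = 1 / sqrt(1 - rho), c2 = 1 / sqrt(1 + (k - 1) * rho))
}

# GLS fit of y ~ group with block-CS correlation rho; vectorized over the
# rows of Y. Returns effect (group coefficient), t, p, df.
gls_group_fit <- function(Y, patient, group01, rho) {
  n <- ncol(Y)
  pat <- factor(patient)
  ni <- as.vector(table(pat))
  ki <- ni[as.integer(pat)]
  c1 <- 1 / sqrt(1 - rho)
  c2 <- 1 / sqrt(1 + (ki - 1) * rho)
  X <- cbind(intercept = 1, group = group01)
  whiten <- function(M) {
    pm <- t(rowsum(t(M), pat)) / rep(ni, each = nrow(M))
    pm_s <- pm[, as.integer(pat), drop = FALSE]
    sweep(M - pm_s, 2, c1, "*") + sweep(pm_s, 2, c2, "*")
  }
  Xs <- whiten(t(X))
  Xs <- t(Xs)
  Ys <- whiten(Y)
  XtXi <- solve(crossprod(Xs))
  H <- XtXi %*% t(Xs)                       # 2 x n
  Bhat <- Ys %*% t(H)                       # features x 2
  fitted <- Bhat %*% t(Xs)
  rss <- rowSums((Ys - fitted)^2)
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  tt <- ifelse(se > 0, Bhat[, 2] / se, NA_real_)
  p <- 2 * stats::pt(-abs(tt), df)
  list(effect = Bhat[, 2], t = tt, p = p, df = df)
}

assoc_stats <- function(feature_id, effect, p) {
  q <- benjamini_hochberg(p)
  data.frame(feature_id = feature_id, effect = effect, p = p, q = q,
             rank = rank(p, ties.method = "first", na.last = "keep"),
             stringsAsFactors = FALSE)
}

#' Patient-aware differential methylation test
#'
#' Tests every CpG for a difference between outcome groups using all samples
#' while accounting for within-patient correlation: (1) a consensus
#' within-patient correlation is estimated once, pooling per-CpG
#' compound-symmetry estimates on the logit (M-value) scale; (2) each CpG is
#' fit by generalized least squares with block compound-symmetry covariance
#' and Wald-tested on the group coefficient; (3) p-values are BH-adjusted
#' across CpGs. No tissue-class covariate is used: all samples of
#' recurrence (or metastasis) patients are contrasted against all samples of
#' the remaining patients.
#'
#' @param beta Beta matrix (probes x samples).
#' @param samples,patients Sample and patient tables.
#' @param outcome `"recurrence"` or `"metastasis"` (patient-level label).
#' @param m_values Test on the logit (M-value) scale instead of beta values
#'   (default FALSE; the effect column is then the difference of group mean
#'   betas rather than the modeled coefficient).
#' @param moderate_variance Optionally shrink per-CpG residual variances 30%
#'   of the way towards their 10%-trimmed mean before the Wald test
#'   (default FALSE; recorded in the result's attributes either way).
#' @return Data frame (feature_id, effect, p, q, rank) with attributes
#'   `consensus_rho`, `m_values`, `moderate_variance`.
#' @export
mixed_group_test <- function(beta, samples, patients,
                             outcome = c("recurrence", "metastasis"),
                             m_values = FALSE, moderate_variance = FALSE) {
  outcome <- match.arg(outcome)
  lab <- stats::setNames(patients[[outcome]], patients$patient_id)
  grp <- lab[samples$patient_id]
  if (anyNA(grp)) stop("samples with patients lacking the outcome label")
  per_pat <- tapply(grp, samples$patient_id, function(g) length(unique(g)))
  if (any(per_pat > 1)) {
    stop("outcome is a patient-level label; a patient has samples in both groups")
  }
  if (length(unique(samples$patient_id[grp])) < 2 ||
      length(unique(samples$patient_id[!grp])) < 2) {
    stop("need at least 2 patients per outcome group")
  }
  beta <- beta[, samples$sample_id, drop = FALSE]
  Ym <- clamp_logit(beta)
  Y <- if (m_values) Ym else beta
  rho <- estimate_consensus_correlation(
    Ym[stats::complete.cases(Ym), , drop = FALSE], samples$patient_id, grp)

  g01 <- as.numeric(grp)
  complete <- stats::complete.cases(Y)
  eff <- p <- rep(NA_real_, nrow(Y))
  if (any(complete)) {
    fit <- gls_group_fit(Y[complete, , drop = FALSE], samples$patient_id,
                         g01, rho)
    if (moderate_variance) {
      # recompute with shrunken variances
      fit <- moderate_gls_fit(Y[complete, , drop = FALSE], samples$patient_id,
                              g01, rho)
    }
    eff[complete] <- fit$effect
    p[complete] <- fit$p
  }
  # pairwise-complete slow path for probes with masked values
  for (j in which(!complete)) {
    ok <- !is.na(Y[j, ])
    if (sum(ok) < 4 || length(unique(g01[ok])) < 2) next
    f <- gls_group_fit(Y[j, ok, drop = FALSE], samples$patient_id[ok],
                       g01[ok], rho)
    eff[j] <- f$effect
    p[j] <- f$p
  }
  if (m_values) {
    mb <- rowMeans(beta[, grp, drop = FALSE], na.rm = TRUE) -
      rowMeans(beta[, !grp, drop = FALSE], na.rm = TRUE)
    eff <- ifelse(is.na(p), NA_real_, mb)
  }
  out <- assoc_stats(rownames(beta), eff, p)
  attr(out, "consensus_rho") <- rho
  attr(out, "m_values") <- m_values
  attr(out, "moderate_variance") <- moderate_variance
  out
}

moderate_gls_fit <- function(Y, patient, g01, rho) {
  fit <- gls_group_fit(Y, patient, g01, rho)
  se0 <- abs(fit$effect / fit$t)
  sigma2 <- se0^2
  target <- mean(sigma2, trim = 0.1, na.rm = TRUE)
  sigma2_mod <- 0.7 * sigma2 + 0.3 * target
  tt <- fit$effect / sqrt(sigma2_mod)
  fit$t <- tt
  fit$p <- 2 * stats::pt(-abs(tt), fit$df)
  fit
}

#' Overlap of the top-ranked features of two result lists
#'
#' @param statsA,statsB Result data frames over the same feature universe,
#'   each with `feature_id` and `rank`.
#' @param top_fraction Fraction in (0, 1] of best-ranked features to take
#'   from each list.
#' @return List with `count` (`|A` intersect `B|`) and `fraction`
#'   (count / floor(top_fraction * n)).
#' @export
rank_overlap <- function(statsA, statsB, top_fraction) {
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  if (!setequal(statsA$feature_id, statsB$feature_id)) {
    stop("result lists must cover the same feature universe")
  }
  k <- floor(top_fraction * nrow(statsA))
  topA <- statsA$feature_id[order(statsA$rank)][seq_len(k)]
  topB <- statsB$feature_id[order(statsB$rank)][seq_len(k)]
  n <- length(intersect(topA, topB))
  list(count = n, fraction = n / k)
}

#' Patient-aware differential expression test on counts
#'
#' Transforms raw counts to log2-CPM with prior count 0.5 and applies the
#' same consensus-correlation GLS test as [mixed_group_test()]. With
#' `grouping = "tissue"` the contrast is cancer vs pooled normal samples (a
#' within-patient contrast; the patient correlation structure is retained).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param samples,patients Sample and patient tables.
#' @param grouping `"recurrence"`, `"metastasis"` (patient-level) or
#'   `"tissue"` (cancer vs normal, sample-level).
#' @return Data frame (feature_id, effect, p, q, rank); effect is the group
#'   difference in log2-CPM. Zero-variance genes get NA statistics.
#' @export
de_mixed_test <- function(counts, samples, patients,
                          grouping = c("recurrence", "metastasis", "tissue")) {
  grouping <- match.arg(grouping)
  counts <- as.matrix(counts[, samples$sample_id, drop = FALSE])
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with library size 0")
  logcpm <- log2(t(t(counts + 0.5) / (lib + 1)) * 1e6)
  if (grouping == "tissue") {
    grp <- samples$tissue_class == "cancer"
  } else {
    lab <- stats::setNames(patients[[grouping]], patients$patient_id)
    grp <- lab[samples$patient_id]
    if (anyNA(grp)) stop("samples with patients lacking the outcome label")
  }
  rho <- estimate_consensus_correlation(logcpm, samples$patient_id, grp)
  fit <- gls_group_fit(logcpm, samples$patient_id, as.numeric(grp), rho)
  novar <- apply(logcpm, 1, function(x) stats::var(x) == 0)
  fit$p[novar] <- NA_real_
  fit$effect[novar] <- NA_real_
  out <- assoc_stats(rownames(counts), fit$effect, fit$p)
  attr(out, "consensus_rho") <- rho
  out
}

#' Correlation between probe methylation and gene expression
#'
#' Pearson correlation between a probe's beta values and its annotated
#' gene's log2-CPM across all matched samples.
#'
#' @param beta Beta matrix.
#' @param counts Gene count matrix.
#' @param cpg_to_gene Data frame with columns `probe_id`, `gene`.
#' @param samples Sample table (defines the matched sample set).
#' @return Data frame (probe_id, gene, r, n_samples); pairs with fewer than
#'   3 matched complete observations get `r = NA`.
#' @export
meth_expr_correlation <- function(beta, counts, cpg_to_gene, samples) {
  shared <- intersect(intersect(colnames(beta), colnames(counts)),
                      samples$sample_id)
  lib <- colSums(counts[, shared, drop = FALSE])
  logcpm <- log2(t(t(counts[, shared, drop = FALSE] + 0.5) / (lib + 1)) * 1e6)
  res <- lapply(seq_len(nrow(cpg_to_gene)), function(i) {
    pid <- cpg_to_gene$probe_id[i]; g <- cpg_to_gene$gene[i]
    if (!pid %in% rownames(beta) || !g %in% rownames(logcpm)) {
      return(data.frame(probe_id = pid, gene = g, r = NA_real_,
                        n_samples = 0L, stringsAsFactors = FALSE))
    }
    x <- beta[pid, shared]; y <- logcpm[g, ]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      NA_real_
    } else {
      stats::cor(x[ok], y[ok])
    }
    data.frame(probe_id = pid, gene = g, r = r, n_samples = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
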