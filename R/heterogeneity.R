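# Intra-/interpatient heterogeneity framework: variability measured by the
# coefficient of variation and similarity measured by Spearman correlation,
# each compared against size-matched random-CpG nulls.

# row-wise CV (n-1 denominator), pairwise-complete
row_cv <- function(M) {
  n <- rowSums(!is.na(M))
  mu <- rowMeans(M, na.rm = TRUE)
  ss <- rowSums(M^2, na.rm = TRUE) - n * mu^2
  s <- sqrt(pmax(ss, 0) / (n - 1))
  ifelse(n >= 2 & mu != 0, s / mu, NA_real_)
}

draw_one_per_patient <- function(samples) {
  vapply(split(samples$sample_id, samples$patient_id),
         function(s) if (length(s) == 1L) s else sample(s, 1L), character(1))
}

#' Interpatient coefficient of variation
#'
#' Per iteration, one sample per patient is drawn uniformly (all tissue
#' classes eligible) and one CV per CpG is computed across the drawn
#' values; the mean CV over `n_iter` iterations is returned.
#'
#' @param beta Beta matrix.
#' @param samples Sample table.
#' @param cpg_set Non-empty character vector of probe ids.
#' @param n_iter Number of random-sampling iterations (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector, mean CV per CpG.
#' @export
interpatient_cv <- function(beta, samples, cpg_set, n_iter = 10L, seed = 1L) {
  if (length(cpg_set) == 0L) stop("empty cpg_set")
  set.seed(seed)
  B <- beta[cpg_set, , drop = FALSE]
  acc <- matrix(0, length(cpg_set), n_iter)
  for (r in seq_len(n_iter)) {
    drawn <- draw_one_per_patient(samples)
    acc[, r] <- row_cv(B[, drawn, drop = FALSE])
  }
  stats::setNames(rowMeans(acc), cpg_set)
}

#' Intrapatient coefficient of variation
#'
#' One CV per CpG across each patient's samples; patients with a single
#' sample cannot contribute and are listed in the skip report.
#'
#' @inheritParams interpatient_cv
#' @return List with `cv` (matrix, contributing patients x CpGs) and
#'   `skipped` (patient ids with fewer than 2 samples).
#' @export
intrapatient_cv <- function(beta, samples, cpg_set) {
  if (length(cpg_set) == 0L) stop("empty cpg_set")
  B <- beta[cpg_set, , drop = FALSE]
  by_pat <- split(samples$sample_id, samples$patient_id)
  skipped <- names(by_pat)[lengths(by_pat) < 2L]
  by_pat <- by_pat[lengths(by_pat) >= 2L]
  cv <- do.call(rbind, lapply(by_pat, function(s) row_cv(B[, s, drop = FALSE])))
  colnames(cv) <- cpg_set
  list(cv = cv, skipped = skipped)
}

#' Size-matched random-CpG null CV distributions
#'
#' Per iteration, `set_size` CpGs are drawn uniformly without replacement
#' from the full filtered universe and the inter- and intrapatient CVs are
#' computed exactly as for a DMC set (including the one-sample-per-patient
#' draw); results are averaged per position over iterations.
#'
#' @inheritParams interpatient_cv
#' @param set_size Number of CpGs per null draw (e.g. 37 or 20).
#' @return List with `inter` (length `set_size`, mean over iterations) and
#'   `intra` (patients x `set_size` matrix, mean over iterations), plus
#'   `skipped` patients.
#' @export
matched_null_cv <- function(beta, samples, set_size, n_iter = 10L, seed = 1L) {
  universe <- rownames(beta)
  if (set_size > length(universe)) stop("set_size exceeds the CpG universe")
  set.seed(seed)
  inter_acc <- NULL; intra_acc <- NULL; skipped <- NULL
  for (r in seq_len(n_iter)) {
    set <- if (set_size == length(universe)) universe else
      universe[sort(sample(length(universe), set_size))]
    drawn <- draw_one_per_patient(samples)
    inter <- row_cv(beta[set, drawn, drop = FALSE])
    intra <- intrapatient_cv(beta, samples, set)
    skipped <- intra$skipped
    inter_acc <- if (is.null(inter_acc)) inter else inter_acc + inter
    intra_acc <- if (is.null(intra_acc)) intra$cv else intra_acc + intra$cv
  }
  list(inter = unname(inter_acc / n_iter), intra = intra_acc / n_iter,
       skipped = skipped)
}

#' Compare two CV distributions
#'
#' Two-sided Wilcoxon rank-sum test between e.g. the DMC CVs and their
#' size-matched null.
#'
#' @param dmc_cvs,null_cvs Non-empty numeric vectors (NAs dropped).
#' @return The [wilcoxon_rank_sum()] result list.
#' @export
compare_cv <- function(dmc_cvs, null_cvs) {
  wilcoxon_rank_sum(as.numeric(dmc_cvs), as.numeric(null_cvs))
}

#' Within-patient methylation similarity
#'
#' Per patient and sample type (cancer; normal = adjacent and distant
#' pooled): Spearman correlation of two samples' beta profiles over
#' `cpg_set`. With fewer than 2 samples of a type the value is NA; with
#' more than 2, two samples are drawn uniformly (fixed per patient per run,
#' seeded). The cancer-vs-normal column correlates the patient's mean
#' cancer profile with the mean normal profile.
#'
#' @inheritParams interpatient_cv
#' @param pool_normal Pool normal_adjacent and normal_distant into one
#'   "normal" type (default TRUE, matching the two-type comparison); FALSE
#'   splits them into separate columns.
#' @return Data frame, one row per patient: rho_cancer, rho_normal (or
#'   rho_normal_adjacent / rho_normal_distant), rho_cancer_vs_normal.
#' @export
intrapatient_correlation <- function(beta, samples, cpg_set, seed = 1L,
                                     pool_normal = TRUE) {
  if (length(cpg_set) < 3L) stop("cpg_set must contain at least 3 CpGs")
  set.seed(seed)
  B <- beta[cpg_set, , drop = FALSE]
  types <- if (pool_normal) {
    list(cancer = "cancer", normal = c("normal_adjacent", "normal_distant"))
  } else {
    list(cancer = "cancer", normal_adjacent = "normal_adjacent",
         normal_distant = "normal_distant")
  }
  pair_rho <- function(ids) {
    if (length(ids) < 2L) return(NA_real_)
    if (length(ids) > 2L) ids <- sample(ids, 2L)
    spearman_rho(B[, ids[1]], B[, ids[2]])
  }
  pats <- unique(samples$patient_id)
  rows <- lapply(pats, function(p) {
    sub <- samples[samples$patient_id == p, ]
    vals <- vapply(types, function(tc) {
      pair_rho(sub$sample_id[sub$tissue_class %in% tc])
    }, numeric(1))
    c_ids <- sub$sample_id[sub$tissue_class == "cancer"]
    n_ids <- sub$sample_id[sub$tissue_class != "cancer"]
    cvn <- if (length(c_ids) >= 1 && length(n_ids) >= 1) {
      spearman_rho(rowMeans(B[, c_ids, drop = FALSE], na.rm = TRUE),
                   rowMeans(B[, n_ids, drop = FALSE], na.rm = TRUE))
    } else NA_real_
    out <- as.data.frame(as.list(vals))
    names(out) <- paste0("rho_", names(types))
    out$rho_cancer_vs_normal <- cvn
    out
  })
  cbind(data.frame(patient_id = pats, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Size-matched random-CpG null correlations
#'
#' Per iteration, `set_size` CpGs are drawn uniformly and
#' [intrapatient_correlation()] is applied; the per-patient mean correlation
#' over `n_iter` iterations (default 100) is returned.
#'
#' @inheritParams intrapatient_correlation
#' @param set_size Number of CpGs per null draw (default 37).
#' @param n_iter Number of random CpG sets (default 100).
#' @return Data frame like [intrapatient_correlation()], values averaged
#'   over iterations.
#' @export
matched_null_correlation <- function(beta, samples, set_size = 37L,
                                     n_iter = 100L, seed = 1L,
                                     pool_normal = TRUE) {
  universe <- rownames(beta)
  if (set_size > length(universe)) stop("set_size exceeds the CpG universe")
  set.seed(seed)
  acc <- NULL
  for (r in seq_len(n_iter)) {
    set <- if (set_size == length(universe)) universe else
      universe[sort(sample(length(universe), set_size))]
    # reuse the ambient RNG stream for the within-type two-sample draws
    s <- sample.int(.Machine$integer.max, 1L)
    res <- intrapatient_correlation(beta, samples, set, seed = s,
                                    pool_normal = pool_normal)
    num <- as.matrix(res[, -1, drop = FALSE])
    acc <- if (is.null(acc)) num else acc + num
  }
  out <- as.data.frame(acc / n_iter)
  cbind(data.frame(patient_id = unique(samples$patient_id),
                   stringsAsFactors = FALSE), out)
}

#' Full heterogeneity report for one DMC set
#'
#' Convenience wrapper producing the CV framework for a DMC set and its
#' size-matched null: per-CpG interpatient CVs, pooled per-(patient, CpG)
#' intrapatient CVs, null counterparts, Wilcoxon comparisons and medians.
#'
#' @inheritParams interpatient_cv
#' @param dmc_set Character vector of DMC probe ids.
#' @param n_iter CV resampling iterations (default 10).
#' @return List with `dmc_inter`, `dmc_intra`, `null_inter`, `null_intra`,
#'   `medians`, `p_inter_vs_null`, `p_intra_vs_null`, `p_inter_vs_intra`,
#'   `n_iter`, `skipped_patients`.
#' @export
cv_report <- function(beta, samples, dmc_set, n_iter = 10L, seed = 1L) {
  dmc_inter <- interpatient_cv(beta, samples, dmc_set, n_iter, seed)
  dmc_intra <- intrapatient_cv(beta, samples, dmc_set)
  null <- matched_null_cv(beta, samples, length(dmc_set), n_iter, seed + 1L)
  di <- as.numeric(dmc_inter)
  da <- as.numeric(dmc_intra$cv)
  list(
    dmc_inter = dmc_inter, dmc_intra = dmc_intra$cv,
    null_inter = null$inter, null_intra = null$intra,
    medians = c(dmc_inter = stats::median(di, na.rm = TRUE),
                dmc_intra = stats::median(da, na.rm = TRUE),
                null_inter = stats::median(null$inter, na.rm = TRUE),
                null_intra = stats::median(as.numeric(null$intra), na.rm = TRUE)),
    p_inter_vs_null = compare_cv(di, null$inter)$p,
    p_intra_vs_null = compare_cv(da, as.numeric(null$intra))$p,
    p_inter_vs_intra = compare_cv(di, da)$p,
    n_iter = n_iter,
    skipped_patients = dmc_intra$skipped)
}
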