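test_that("with one sample per patient the mixed test reduces to the two-sample t-test", {
  set.seed(61)
  n_pat <- 14
  patients <- patient_table(data.frame(
    patient_id = sprintf("P%02d", 1:n_pat),
    recurrence = rep(c(TRUE, FALSE), each = n_pat / 2),
    metastasis = FALSE))
  samples <- sample_table(data.frame(
    sample_id = sprintf("P%02d_S1", 1:n_pat),
    patient_id = patients$patient_id,
    tissue_class = "cancer", cancer_area_pct = 50))
  beta <- beta_matrix(matrix(runif(40 * n_pat, 0.2, 0.8), 40, n_pat,
                             dimnames = list(sprintf("cg%02d", 1:40),
                                             samples$sample_id)))
  res <- mixed_group_test(beta, samples, patients, "recurrence")
  expect_equal(attr(res, "consensus_rho"), 0)
  g <- patients$recurrence
  for (j in c(1, 7, 25)) {
    fit <- summary(lm(beta[j, ] ~ g))
    expect_equal(res$p[j], fit$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(res$effect[j], unname(fit$coefficients[2, 1]),
                 tolerance = 1e-10)
  }
})

test_that("the GLS test agrees with limma's block-correlation fit given the same rho", {
  skip_if_not_installed("limma")
  co <- small_cohort(seed = 62, n_probes = 150)
  res <- mixed_group_test(co$beta, co$samples, co$patients, "recurrence")
  rho <- attr(res, "consensus_rho")
  grp <- stats::setNames(co$patients$recurrence,
                         co$patients$patient_id)[co$samples$patient_id]
  design <- cbind(1, as.numeric(grp))
  fit <- limma::lmFit(co$beta, design, block = co$samples$patient_id,
                      correlation = rho)
  t_limma <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
  p_limma <- 2 * pt(-abs(t_limma), fit$df.residual)
  expect_equal(unname(res$p), unname(p_limma), tolerance = 1e-8)
  expect_equal(unname(res$effect), unname(fit$coefficients[, 2]),
               tolerance = 1e-8)
})

test_that("mixed test statistics are invariant to sample order and group relabeling", {
  co <- small_cohort(seed = 63, n_probes = 80)
  res <- mixed_group_test(co$beta, co$samples, co$patients, "recurrence")
  perm <- sample(nrow(co$samples))
  res_perm <- mixed_group_test(co$beta[, perm, drop = FALSE],
                               co$samples[perm, ], co$patients, "recurrence")
  expect_equal(res$p, res_perm$p, tolerance = 1e-12)
  flipped <- co$patients
  flipped$recurrence <- !flipped$recurrence
  flipped$metastasis <- FALSE
  res_flip <- mixed_group_test(co$beta, co$samples, flipped, "recurrence")
  expect_equal(res$p, res_flip$p, tolerance = 1e-10)
  expect_equal(res$effect, -res_flip$effect, tolerance = 1e-10)
})

test_that("outcome tests validate the patient-level design", {
  co <- small_cohort(seed = 64, n_probes = 30)
  one_group <- co$patients
  one_group$recurrence <- c(TRUE, rep(FALSE, 15))
  expect_error(mixed_group_test(co$beta, co$samples, one_group, "recurrence"),
               "2 patients per outcome group")
})

test_that("rank overlap follows set arithmetic on ranked lists", {
  mk <- function(ids, p) {
    data.frame(feature_id = ids, effect = 0, p = p,
               q = benjamini_hochberg(p),
               rank = rank(p, ties.method = "first"))
  }
  ids <- sprintf("f%02d", 1:10)
  a <- mk(ids, seq(0.01, 0.1, by = 0.01))
  expect_equal(rank_overlap(a, a, 0.5), list(count = 5, fraction = 1))
  expect_equal(rank_overlap(a, a, 1)$fraction, 1)
  # top-5 of B shares exactly f01, f02 with top-5 of A
  b <- mk(ids, c(0.01, 0.02, 0.9, 0.91, 0.92, 0.93, 0.94, 0.03, 0.04, 0.05))
  ov <- rank_overlap(a, b, 0.5)
  expect_equal(ov$count, 2)
  expect_equal(ov$fraction, 0.4)
  expect_error(rank_overlap(a, b, 0), "top_fraction")
  expect_error(rank_overlap(a, b[1:9, ], 0.5), "universe")
})

test_that("expression test finds tissue signal, stays null without signal", {
  co <- small_cohort(seed = 65, n_probes = 300)
  genes <- unique(co$annotation$gene_symbols)
  de_genes <- grep("^RGENE", genes, value = TRUE)
  cnt <- generate_counts(co$samples, genes, tissue_de_genes = de_genes,
                         lfc = 2, seed = 66)
  res_t <- de_mixed_test(cnt$counts, co$samples, co$patients, "tissue")
  hits <- res_t$feature_id[!is.na(res_t$q) & res_t$q < 0.05]
  expect_gt(mean(cnt$tissue_de_genes %in% hits), 0.8)
  # outcome contrast on tissue-only signal: essentially nothing
  res_o <- de_mixed_test(cnt$counts, co$samples, co$patients, "recurrence")
  expect_lt(sum(res_o$q < 0.05, na.rm = TRUE), 0.02 * nrow(res_o))
  # degenerate inputs
  cnt0 <- cnt$counts
  cnt0[, 1] <- 0
  expect_error(de_mixed_test(cnt0, co$samples, co$patients, "tissue"),
               "library size 0")
})

test_that("identical counts everywhere yield a flagged NA statistic", {
  co <- small_cohort(seed = 67, n_probes = 30)
  counts <- matrix(7L, 2, nrow(co$samples),
                   dimnames = list(c("gA", "gB"), co$samples$sample_id))
  res <- de_mixed_test(counts, co$samples, co$patients, "tissue")
  expect_true(all(is.na(res$p)))
})

test_that("methylation-expression correlation recovers exact linear relations", {
  co <- small_cohort(seed = 68, n_probes = 40)
  probes <- rownames(co$beta)[1:3]
  lib <- 1e6
  # gene g1 exactly linear in probe 1's betas on the log-CPM scale
  counts <- matrix(0, 3, nrow(co$samples),
                   dimnames = list(c("g1", "g2", "g3"), co$samples$sample_id))
  counts[1, ] <- round(2^(5 + 4 * co$beta[probes[1], ]) * 50)
  counts[2, ] <- round(2^(10 - 4 * co$beta[probes[2], ]) * 50)
  # filler gene keeping every library size identical, so log-CPM is an
  # affine function of the log counts
  counts[3, ] <- 3e5 - counts[1, ] - counts[2, ]
  map <- data.frame(probe_id = probes, gene = c("g1", "g2", "g3"))
  res <- meth_expr_correlation(co$beta, counts, map, co$samples)
  expect_gt(res$r[1], 0.99)
  expect_lt(res$r[2], -0.99)
  expect_lt(abs(res$r[3]), 0.6)
  # independent pairs average near zero
  set.seed(69)
  nullc <- matrix(rpois(100 * nrow(co$samples), 200), 100,
                  dimnames = list(sprintf("n%03d", 1:100),
                                  co$samples$sample_id))
  nullmap <- data.frame(probe_id = rownames(co$beta)[4:40][1:37],
                        gene = rownames(nullc)[1:37])
  nullres <- meth_expr_correlation(co$beta, nullc, nullmap, co$samples)
  expect_lt(abs(mean(nullres$r)), 0.1)
  # fewer than 3 matched samples: NA flagged
  tiny <- co$samples[1:2, ]
  res2 <- meth_expr_correlation(co$beta[, 1:2], counts[, 1:2], map, tiny)
  expect_true(all(is.na(res2$r)))
})
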