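test_that("interpatient CV: constant data give zero, resampling is seeded", {
  co <- small_cohort(seed = 71, n_probes = 60)
  flat <- beta_matrix(matrix(0.4, 10, nrow(co$samples),
                             dimnames = list(sprintf("cg%02d", 1:10),
                                             co$samples$sample_id)))
  cv0 <- interpatient_cv(flat, co$samples, rownames(flat), seed = 1)
  expect_equal(unname(cv0), rep(0, 10))
  a <- interpatient_cv(co$beta, co$samples, rownames(co$beta)[1:20], seed = 5)
  b <- interpatient_cv(co$beta, co$samples, rownames(co$beta)[1:20], seed = 5)
  expect_identical(a, b)
  expect_error(interpatient_cv(co$beta, co$samples, character(0)), "empty")
})

test_that("one sample per patient removes sampling randomness from the interpatient CV", {
  samples <- sample_table(data.frame(
    sample_id = c("a", "b", "c"), patient_id = c("P1", "P2", "P3"),
    tissue_class = "cancer", cancer_area_pct = 50))
  beta <- beta_matrix(matrix(c(0.2, 0.4, 0.9), 1, 3,
                             dimnames = list("cg1", c("a", "b", "c"))))
  got <- interpatient_cv(beta, samples, "cg1", n_iter = 10, seed = 3)
  x <- c(0.2, 0.4, 0.9)
  expect_equal(unname(got), sd(x) / mean(x))
})

test_that("intrapatient CV covers multi-sample patients and reports skips", {
  co <- small_cohort(seed = 72, n_probes = 40)
  res <- intrapatient_cv(co$beta, co$samples, rownames(co$beta)[1:10])
  expect_length(res$skipped, 0L)
  expect_equal(nrow(res$cv), 16L)
  # add a single-sample patient: skipped, not present in the matrix
  extra_samples <- rbind(co$samples,
                         data.frame(sample_id = "X1", patient_id = "P99",
                                    tissue_class = "cancer",
                                    cancer_area_pct = 50))
  extra_beta <- cbind(co$beta, X1 = runif(nrow(co$beta), 0.2, 0.8))
  res2 <- intrapatient_cv(extra_beta, extra_samples, rownames(co$beta)[1:10])
  expect_equal(res2$skipped, "P99")
  expect_false("P99" %in% rownames(res2$cv))
  # two-sample oracle
  two <- sample_table(data.frame(sample_id = c("s1", "s2"),
                                 patient_id = "P1", tissue_class = "cancer",
                                 cancer_area_pct = 10))
  bm <- beta_matrix(matrix(c(0.3, 0.5), 1, 2,
                           dimnames = list("cg1", c("s1", "s2"))))
  got <- intrapatient_cv(bm, two, "cg1")
  expect_equal(unname(got$cv["P1", "cg1"]), sd(c(0.3, 0.5)) / 0.4)
})

test_that("matched null CV reduces to the full-universe CVs when there is no choice", {
  co <- small_cohort(seed = 73, n_probes = 25)
  null <- matched_null_cv(co$beta, co$samples, set_size = nrow(co$beta),
                          n_iter = 10, seed = 9)
  inter_direct <- interpatient_cv(co$beta, co$samples, rownames(co$beta),
                                  n_iter = 10, seed = 9)
  intra_direct <- intrapatient_cv(co$beta, co$samples, rownames(co$beta))
  expect_equal(null$inter, unname(inter_direct))
  expect_equal(null$intra, intra_direct$cv)
  expect_error(matched_null_cv(co$beta, co$samples, set_size = 26), "universe")
  expect_identical(matched_null_cv(co$beta, co$samples, 10, seed = 4),
                   matched_null_cv(co$beta, co$samples, 10, seed = 4))
})

test_that("spiked CpGs separate interpatient from intrapatient variation", {
  cfg <- simulation_config(n_probes = 2000, sigma_intra = 0.022, seed = 74)
  co <- generate_cohort(cfg)
  rep <- cv_report(co$beta, co$samples, co$truth$recurrence_dmcs, seed = 75)
  expect_lt(rep$medians["dmc_intra"], rep$medians["dmc_inter"])
  expect_gt(rep$medians["dmc_inter"], rep$medians["null_inter"])
  expect_lt(rep$p_inter_vs_intra, 1e-6)
  expect_lt(rep$p_inter_vs_null, 1e-6)
})

test_that("within-patient correlations handle duplicates, missing types and seeding", {
  co <- small_cohort(seed = 76, n_probes = 50)
  cpgs <- rownames(co$beta)[1:20]
  # duplicate samples correlate perfectly
  p1 <- co$samples$patient_id[1]
  ids <- co$samples$sample_id[co$samples$patient_id == p1 &
                                co$samples$tissue_class == "cancer"]
  dup_beta <- co$beta
  if (length(ids) >= 2) dup_beta[, ids[2]] <- dup_beta[, ids[1]]
  res <- intrapatient_correlation(dup_beta, co$samples, cpgs, seed = 1)
  # cancer pair for p1 is drawn among duplicates only when exactly 2 exist
  two_cancer <- co$samples[co$samples$patient_id == p1, ]
  if (sum(two_cancer$tissue_class == "cancer") == 2) {
    expect_equal(res$rho_cancer[res$patient_id == p1], 1)
  }
  # single normal sample leaves NA
  drop_one <- co$samples[!(co$samples$patient_id == p1 &
                             co$samples$tissue_class == "normal_distant"), ]
  res2 <- intrapatient_correlation(co$beta, drop_one, cpgs, seed = 1)
  pooled_n <- sum(drop_one$patient_id == p1 &
                    drop_one$tissue_class != "cancer")
  if (pooled_n < 2) {
    expect_true(is.na(res2$rho_normal[res2$patient_id == p1]))
  }
  expect_identical(intrapatient_correlation(co$beta, co$samples, cpgs, seed = 8),
                   intrapatient_correlation(co$beta, co$samples, cpgs, seed = 8))
  expect_error(intrapatient_correlation(co$beta, co$samples, cpgs[1:2]),
               "at least 3")
})

test_that("null correlations average the per-iteration reports", {
  co <- small_cohort(seed = 77, n_probes = 30)
  # no choice of CpGs: a single iteration equals the direct report
  set.seed(12)
  s <- sample.int(.Machine$integer.max, 1L)
  direct <- intrapatient_correlation(co$beta, co$samples, rownames(co$beta),
                                     seed = s)
  null1 <- matched_null_correlation(co$beta, co$samples,
                                    set_size = nrow(co$beta), n_iter = 1,
                                    seed = 12)
  expect_equal(as.matrix(null1[, -1]), as.matrix(direct[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # mean over iterations lies within the per-iteration range
  nullN <- matched_null_correlation(co$beta, co$samples, set_size = 10,
                                    n_iter = 5, seed = 13)
  expect_true(all(abs(as.matrix(nullN[, -1])) <= 1 | is.na(as.matrix(nullN[, -1]))))
  expect_identical(matched_null_correlation(co$beta, co$samples, 10, 3, seed = 2),
                   matched_null_correlation(co$beta, co$samples, 10, 3, seed = 2))
})

test_that("heterogeneity reports round-trip through TSV", {
  co <- small_cohort(seed = 78, n_probes = 40)
  res <- intrapatient_correlation(co$beta, co$samples, rownames(co$beta)[1:10],
                                  seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$rho_cancer, res$rho_cancer, tolerance = 1e-12)
  expect_identical(back$patient_id, res$patient_id)
})
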