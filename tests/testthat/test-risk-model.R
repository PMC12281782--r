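# compact survival scenario used across the risk-model tests
risk_scenario <- function(seed = 81L, n = 40L, p = 8L, signal = 1.2) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.1, 0.9), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("cg%02d", seq_len(p))))
  eta <- signal * scale(X[, 1])[, 1]
  tm <- rexp(n, 0.01 * exp(eta))
  cens <- runif(n, 96, 192)
  surv <- survival_table(rownames(X), pmin(tm, cens), tm <= cens)
  list(X = X, surv = surv)
}

test_that("LOOCV runs one iteration per unit and is order-invariant", {
  sc <- risk_scenario(seed = 81, n = 24, p = 5)
  sel <- loocv_selection(sc$X, sc$surv, seed = 4)
  expect_equal(nrow(sel$coefficients) + length(sel$skipped), 24L)
  expect_setequal(rownames(sel$coefficients),
                  setdiff(rownames(sc$X), sel$skipped))
  perm <- sample(nrow(sc$X))
  sel_perm <- loocv_selection(sc$X[perm, ], sc$surv, seed = 4)
  expect_equal(colMeans(sel$coefficients != 0),
               colMeans(sel_perm$coefficients != 0))
})

test_that("pure-noise candidates never reach majority selection", {
  for (seed in 91:93) {
    set.seed(seed)
    n <- 30; p <- 10
    X <- matrix(runif(n * p, 0.1, 0.9), n, p,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%02d", 1:p)))
    tm <- rexp(n, 0.01); cens <- runif(n, 96, 192)
    surv <- survival_table(rownames(X), pmin(tm, cens), tm <= cens)
    sel <- loocv_selection(X, surv, seed = seed)
    expect_true(all(colMeans(sel$coefficients != 0) <= 0.5))
  }
})

test_that("a dominant covariate is always selected", {
  sc <- risk_scenario(seed = 94, n = 40, p = 6, signal = 2)
  sel <- loocv_selection(sc$X, sc$surv, seed = 5)
  freq <- colMeans(sel$coefficients != 0)
  expect_equal(unname(freq["cg01"]), 1)
})

test_that("final-model assembly applies the strict majority rule and mean-of-nonzeros", {
  cm <- rbind(c(0.2, 0.1, 0.0),
              c(0.0, 0.2, 0.0),
              c(0.4, 0.3, 0.0),
              c(0.0, 0.4, 0.0))
  colnames(cm) <- c("cgA", "cgB", "cgC")
  X <- matrix(runif(4 * 3, 0.2, 0.8), 4, 3,
              dimnames = list(paste0("u", 1:4), colnames(cm)))
  surv <- survival_table(rownames(X), c(10, 20, 30, 40),
                         c(TRUE, TRUE, FALSE, TRUE))
  model <- build_final_model(cm, X, surv)
  # cgA nonzero in exactly 50% of iterations: excluded (strict >)
  expect_identical(model$probes, "cgB")
  expect_equal(unname(model$coefficients), mean(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(unname(model$selection_frequency),
               c(0.5, 1, 0))
  # mean of nonzero coefficients on a toy column
  cm2 <- matrix(c(0.2, 0, 0.4), 3, 1, dimnames = list(NULL, "cgZ"))
  X2 <- matrix(runif(3), 3, 1, dimnames = list(paste0("u", 1:3), "cgZ"))
  s2 <- survival_table(rownames(X2), 1:3, c(TRUE, TRUE, TRUE))
  m2 <- build_final_model(cm2, X2, s2)
  expect_equal(unname(m2$coefficients), 0.3)
  # empty model is an error
  none <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(build_final_model(none, X, surv), "empty model")
})

test_that("the median cutoff splits even cohorts in half with ties going high-risk", {
  set.seed(95)
  n <- 20
  X <- matrix(runif(n), n, 1, dimnames = list(sprintf("u%02d", 1:n), "cg1"))
  cm <- matrix(rep(0.5, 6), 6, 1, dimnames = list(NULL, "cg1"))
  surv <- survival_table(rownames(X), sample(10:90, n), runif(n) < 0.7)
  model <- build_final_model(cm, X, surv)
  strat <- stratify_and_test(model, X, surv)
  expect_equal(sort(as.vector(table(strat$groups$risk_group))), c(10, 10))
  # a unit exactly at the cutoff lands in the high-risk group
  X2 <- rbind(X, u99 = model$cutoff / 0.5)
  surv2 <- survival_table(c(surv$unit_id, "u99"), c(surv$time_months, 50),
                          c(surv$event, TRUE))
  strat2 <- stratify_and_test(model, X2, surv2)
  expect_equal(strat2$groups$risk_group[strat2$groups$unit_id == "u99"],
               "high")
})

test_that("degenerate stratification errors are surfaced with context and labels are symmetric", {
  n <- 12
  X <- matrix(0.5, n, 1, dimnames = list(sprintf("u%02d", 1:n), "cg1"))
  cm <- matrix(rep(1, 4), 4, 1, dimnames = list(NULL, "cg1"))
  surv <- survival_table(rownames(X), seq(10, 120, by = 10), rep(TRUE, n))
  model <- build_final_model(cm, X, surv)
  expect_error(stratify_and_test(model, X, surv), "one risk group")
  # label symmetry of the split test
  sc <- risk_scenario(seed = 96, n = 30, p = 3, signal = 1.5)
  sel <- loocv_selection(sc$X, sc$surv, seed = 6)
  m <- build_final_model(sel$coefficients, sc$X, sc$surv)
  strat <- stratify_and_test(m, sc$X, sc$surv)
  relabel <- ifelse(strat$groups$risk_group == "high", "low", "high")
  ix <- match(strat$groups$unit_id, sc$surv$unit_id)
  lr <- logrank_test(sc$surv$time_months[ix], sc$surv$event[ix], relabel)
  expect_equal(lr$p, strat$p)
})

test_that("with the penalty forced off a single candidate matches the unpenalized Cox fit", {
  sc <- risk_scenario(seed = 97, n = 30, p = 1, signal = 1.5)
  fit <- penalized_cox_fit(sc$X, sc$surv$time_months, sc$surv$event,
                           l1_ratio = 0.1, lambda = 0)
  cph <- survival::coxph(survival::Surv(sc$surv$time_months, sc$surv$event) ~
                           sc$X, ties = "breslow")
  expect_lt(abs(unname(fit$coefficients) - unname(coef(cph))), 1e-4)
})
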