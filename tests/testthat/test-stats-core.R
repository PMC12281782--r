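test_that("coefficient of variation matches the direct formula and its edge cases", {
  expect_equal(coefficient_of_variation(c(0.5, 0.5, 0.5)), 0)
  x <- c(0.2, 0.4)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  expect_equal(round(coefficient_of_variation(x), 4), 0.4714)
  expect_warning(out <- coefficient_of_variation(c(-0.1, 0.1)), "undefined")
  expect_true(is.na(out))
  expect_error(coefficient_of_variation(0.3), "at least 2")
  # scale invariance
  set.seed(1)
  for (i in 1:10) {
    x <- runif(8, 0.1, 0.9)
    c_pos <- runif(1, 0.1, 10)
    expect_equal(coefficient_of_variation(c_pos * x),
                 coefficient_of_variation(x))
  }
})

test_that("spearman correlation equals rank-then-Pearson, with tie handling", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)
  x <- c(1, 2, 2, 4); y <- c(4, 1, 2, 3)
  # mid-rank oracle: Pearson correlation of average ranks
  oracle <- cor(rank(x), rank(y))
  expect_equal(spearman_rho(x, y), oracle)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  # invariance under strictly monotone transforms
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
    expect_equal(spearman_rho(a, qlogis(plogis(b))), spearman_rho(a, b))
  }
  expect_warning(out <- spearman_rho(c(1, 1, 1), 1:3), "zero rank variance")
  expect_true(is.na(out))
})

test_that("wilcoxon rank-sum: exact enumeration, symmetry, and the two paths agree", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 6)
  same <- wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$p, 1)
  # exact path vs base R's exact test on random tie-free samples
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:100, 5); b <- sample(101:200, 4) - 100.5
    mine <- wilcoxon_rank_sum(a, b)
    base_r <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$statistic, unname(base_r$statistic))
    expect_equal(mine$p, base_r$p.value)
  }
  # normal-approximation path close to exact for moderate n
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    exact_p <- wilcoxon_rank_sum(a, b)$p
    approx_p <- wilcoxon_rank_sum(c(a, rnorm(1)), b)$p  # n = 13 forces normal
    # compare the two paths on the same data by enlarging past the cutoff
    big <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(wilcoxon_rank_sum(a, b, "two_sided")$p - big), 0.02)
  }
  # tie-corrected normal path against base R with ties
  set.seed(5)
  a <- sample(1:5, 15, TRUE); b <- sample(2:6, 12, TRUE)
  expect_equal(wilcoxon_rank_sum(a, b)$p,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
})

test_that("hypergeometric upper tail matches exhaustive enumeration and phyper", {
  # enumeration oracle: all C(pop_n, draws) subsets
  enum_tail <- function(pop_n, pop_success, draws, observed) {
    marked <- seq_len(pop_success)
    combos <- utils::combn(pop_n, draws)
    mean(colSums(matrix(combos %in% marked, nrow = draws)) >= observed)
  }
  expect_equal(hypergeometric_upper_tail(10, 4, 3, 3), 4 / 120)
  expect_equal(hypergeometric_upper_tail(10, 4, 3, 3), enum_tail(10, 4, 3, 3))
  expect_equal(hypergeometric_upper_tail(10, 4, 3, 0), 1)
  expect_equal(hypergeometric_upper_tail(5, 5, 5, 5), 1)
  for (pop in c(6, 9, 12)) {
    for (succ in c(2, pop %/% 2)) {
      for (draws in c(2, pop %/% 3)) {
        for (obs in 0:min(draws, succ)) {
          expect_equal(hypergeometric_upper_tail(pop, succ, draws, obs),
                       enum_tail(pop, succ, draws, obs))
          expect_equal(hypergeometric_upper_tail(pop, succ, draws, obs),
                       phyper(obs - 1, succ, pop - succ, draws,
                              lower.tail = FALSE))
        }
      }
    }
  }
  expect_error(hypergeometric_upper_tail(10, 11, 3, 1), "inconsistent")
  expect_error(hypergeometric_upper_tail(10, 4, 3, 4), "inconsistent")
  # tails and point mass sum to one
  expect_equal(hypergeometric_upper_tail(8, 3, 4, 2) +
                 phyper(1, 3, 5, 4), 1)
})

test_that("benjamini-hochberg equals the step-up formula and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, p.adjust(p, "BH"))
    # step-up formula oracle, written independently
    o <- order(p)
    m <- length(p)
    q_oracle <- numeric(m)
    for (k in seq_len(m)) {
      js <- which(p >= p[o][k])  # ranks in sorted order with p_(j) >= p_(i)
      q_oracle[o][k] <- min(1, min(m * sort(p)[sort(p) >= p[o][k]] /
                                     which(sort(p) >= p[o][k])))
    }
    expect_equal(q, q_oracle)
    expect_true(all(q >= p))
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  # NA propagation
  expect_equal(benjamini_hochberg(c(0.02, NA, 0.04)),
               p.adjust(c(0.02, NA, 0.04), "BH"))
})

test_that("log-rank statistic matches the risk-set tabulation and survdiff", {
  # identical groups: observed equals expected
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  g <- rep(c("A", "B"), each = 3)
  expect_equal(logrank_test(tm, ev, g)$chi_square, 0)
  # all censored: flagged, not an error
  r <- logrank_test(c(5, 6, 7, 8), rep(FALSE, 4), rep(c("A", "B"), 2))
  expect_true(r$no_events)
  expect_equal(r$p, 1)
  expect_error(logrank_test(1:3, rep(TRUE, 3), rep("A", 3)), "two groups")
  # 6-subject toy against a hand risk-set tabulation
  tm <- 1:6; ev <- rep(TRUE, 6); g <- rep(c("A", "B"), each = 3)
  O1 <- E1 <- V <- 0
  for (t in 1:6) {
    at <- tm >= t
    n <- sum(at); n1 <- sum(at & g == "A")
    d <- 1
    O1 <- O1 + as.numeric(ev[t] && g[t] == "A")
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(logrank_test(tm, ev, g)$chi_square, (O1 - E1)^2 / V)
  # against survival::survdiff on random data, with ties
  set.seed(7)
  for (i in 1:10) {
    tm <- sample(1:8, 20, TRUE); ev <- runif(20) < 0.7
    g <- sample(c("A", "B"), 20, TRUE)
    if (length(unique(g)) < 2 || !any(ev)) next
    sd_chi <- survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq
    expect_equal(logrank_test(tm, ev, g)$chi_square, sd_chi)
  }
})
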