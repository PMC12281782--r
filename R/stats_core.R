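#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, the
#' scale-free dispersion measure used throughout the heterogeneity analyses.
#' Missing values are dropped before computation.
#'
#' @param x Numeric vector with at least two non-missing values.
#' @return A single non-negative number, or `NA_real_` (with a warning) when
#'   the mean is zero and the ratio is undefined.
#' @examples
#' coefficient_of_variation(c(0.2, 0.4))
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop("coefficient_of_variation() needs at least 2 non-missing values")
  }
  m <- mean(x)
  if (m == 0) {
    warning("mean is zero; coefficient of variation undefined")
    return(NA_real_)
  }
  stats::sd(x) / m
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), computed on
#' pairwise-complete observations.
#'
#' @param x,y Numeric vectors of equal length with at least 3 complete pairs.
#' @return A number in `[-1, 1]`, or `NA_real_` (with a warning) when either
#'   vector has zero rank variance.
#' @examples
#' spearman_rho(1:4, c(4, 1, 2, 3))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NA_real_)
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(x) - 1L) * sx * sy)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p-value by enumeration of all rank assignments when
#' `length(a) + length(b) <= 12` and the pooled data contain no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The statistic is the Mann-Whitney U for the first sample.
#'
#' @param a,b Non-empty numeric vectors.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (of `a` vs `b`).
#' @return List with `statistic` (U), `p`, and `method` ("exact" or "normal").
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (na + nb <= 12L && !ties) {
    # enumerate all C(na+nb, na) assignments of ranks to sample a
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(seq_len(na + nb)[combos], nrow = na)) -
      na * (na + 1) / 2
    p <- switch(alternative,
      two_sided = {
        mu <- na * nb / 2
        mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
      },
      less = mean(u_all <= U + 1e-9),
      greater = mean(u_all >= U - 1e-9)
    )
    return(list(statistic = U, p = p, method = "exact"))
  }
  # normal approximation with tie correction
  n <- na + nb
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p = 1, method = "normal"))
  sigma <- sqrt(sigma2)
  z <- switch(alternative,
    two_sided = (abs(U - mu) - 0.5) / sigma,
    less = (U - mu + 0.5) / sigma,
    greater = (U - mu - 0.5) / sigma
  )
  p <- switch(alternative,
    two_sided = 2 * stats::pnorm(max(z, 0), lower.tail = FALSE),
    less = stats::pnorm(z),
    greater = stats::pnorm(z, lower.tail = FALSE)
  )
  list(statistic = U, p = min(p, 1), method = "normal")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= observed)` when drawing `draws` balls from a population of
#' `pop_n` with `pop_success` marked, the enrichment p-value used for
#' chromatin-state and TF-binding-region tests.
#'
#' @param pop_n Population size.
#' @param pop_success Number of marked elements in the population.
#' @param draws Sample size drawn without replacement.
#' @param observed Observed number of marked elements in the sample.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeometric_upper_tail(10, 4, 3, 3)  # 4/120
#' @export
hypergeometric_upper_tail <- function(pop_n, pop_success, draws, observed) {
  if (pop_success > pop_n || draws > pop_n || observed < 0 ||
      observed > min(draws, pop_success)) {
    stop("inconsistent hypergeometric counts")
  }
  if (observed == 0) return(1)
  ks <- observed:min(draws, pop_success)
  # sum of point masses via log binomial coefficients for stability
  logp <- lchoose(pop_success, ks) + lchoose(pop_n - pop_success, draws - ks) -
    lchoose(pop_n, draws)
  min(sum(exp(logp)), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / rank(j)`, capped at 1, returned
#' in the input order. `NA` p-values yield `NA` q-values and do not count
#' towards `m`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (length(p) && (any(p < 0) || any(p > 1))) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  m <- length(p)
  if (m > 0L) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
  }
  q
}

#' Two-group log-rank test
#'
#' Standard (unstratified) log-rank statistic over the pooled event times,
#' with p-value from the chi-square distribution with 1 degree of freedom.
#'
#' @param time Positive event/censoring times.
#' @param event Logical event indicators (TRUE = event observed).
#' @param group Two-level factor/vector of group labels.
#' @return List with `chi_square`, `p`, `observed` and `expected` (per
#'   group), and `no_events` flag. With zero events the result is flagged
#'   (`no_events = TRUE`, `p = 1`) rather than an error.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) == 0L)) stop("a group with zero subjects")
  event <- as.logical(event)
  if (!any(event)) {
    return(list(chi_square = NA_real_, p = 1,
                observed = c(0, 0), expected = c(0, 0), no_events = TRUE))
  }
  g1 <- group == levels(group)[1L]
  times <- sort(unique(time[event]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    return(list(chi_square = 0, p = 1,
                observed = c(O1, sum(event) - O1),
                expected = c(E1, sum(event) - E1), no_events = FALSE))
  }
  chi <- (O1 - E1)^2 / V
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = c(O1, sum(event) - O1),
       expected = c(E1, sum(event) - E1), no_events = FALSE)
}
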