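# Elastic-net penalized Cox regression (Breslow ties) via iteratively
# reweighted least squares with cyclic coordinate descent, plus a
# regularization path and k-fold cross-validation of the penalized
# partial-likelihood deviance.

#' Breslow partial log-likelihood
#'
#' @param eta Linear predictor per subject.
#' @param time Event/censoring times.
#' @param event Logical event indicators.
#' @return The Breslow-ties Cox partial log-likelihood.
#' @export
cox_partial_loglik <- function(eta, time, event) {
  event <- as.logical(event)
  if (!any(event)) return(0)
  theta <- exp(eta)
  ut <- sort(unique(time[event]))
  s0 <- vapply(ut, function(t) sum(theta[time >= t]), numeric(1))
  d <- vapply(ut, function(t) sum(event & time == t), numeric(1))
  sum(eta[event]) - sum(d * log(s0))
}

# per-subject gradient g and diagonal-Hessian h of the Breslow partial
# log-likelihood wrt eta (vectorized over risk sets)
cox_eta_derivs <- function(eta, time, event) {
  theta <- exp(eta)
  ut <- sort(unique(time[event]))
  s0 <- vapply(ut, function(t) sum(theta[time >= t]), numeric(1))
  d <- vapply(ut, function(t) sum(event & time == t), numeric(1))
  # A_i = sum over event times s <= t_i of d_s / S0(s); B_i likewise with S0^2
  ca <- cumsum(d / s0)
  cb <- cumsum(d / s0^2)
  idx <- findInterval(time, ut)          # number of event times <= t_i
  A <- ifelse(idx > 0, ca[pmax(idx, 1L)], 0)
  B <- ifelse(idx > 0, cb[pmax(idx, 1L)], 0)
  g <- as.numeric(event) - theta * A
  h <- theta * A - theta^2 * B
  list(g = g, h = pmax(h, 0))
}

#' Elastic-net penalized Cox model fit
#'
#' Maximizes the Breslow-ties Cox partial log-likelihood penalized by
#' `lambda * (l1_ratio * ||b||_1 + (1 - l1_ratio)/2 * ||b||_2^2)` (objective
#' scaled as `-logpl/n + penalty`, the glmnet convention). Features are
#' standardized internally (n-denominator SD); coefficients are returned on
#' the original scale. The fit is deterministic for fixed inputs, and the
#' penalized objective is monitored to be non-increasing across iterations
#' (with step-halving as the safeguard).
#'
#' @param X Numeric matrix, units x features, no missing values.
#' @param time,event Survival outcome per unit; at least one event.
#' @param l1_ratio Elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Non-negative penalty strength.
#' @param standardize Standardize columns before fitting (default TRUE).
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @param beta_init Optional warm-start coefficients on the original scale
#'   (e.g. the solution at the previous lambda of a path).
#' @return List with `coefficients` (original scale), `n_iter`, `objective`
#'   (trace, standardized scale) and `converged`.
#' @export
penalized_cox_fit <- function(X, time, event, l1_ratio = 0.1, lambda = 0,
                              standardize = TRUE, max_iter = 200L,
                              tol = 1e-8, beta_init = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  event <- as.logical(event)
  if (!any(event)) stop("at least one event is required")
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- if (standardize) sqrt(colMeans(sweep(X, 2, ctr)^2)) else rep(1, p)
  keep <- scl > 0                       # constant columns get coefficient 0
  Xs <- sweep(X[, keep, drop = FALSE], 2, ctr[keep])
  Xs <- sweep(Xs, 2, scl[keep], "/")
  pk <- ncol(Xs)

  beta0 <- if (is.null(beta_init)) numeric(pk) else beta_init[keep] * scl[keep]
  ord <- order(time)
  core <- .cox_cd_core(Xs[ord, , drop = FALSE], time[ord],
                       as.integer(event[ord]), l1_ratio, lambda, beta0,
                       max_iter, tol)
  obj_trace <- core$objective
  if (!core$converged &&
      max(abs(utils::tail(diff(obj_trace), 3))) > 1e-6) {
    stop(sprintf(
      "penalized_cox_fit did not converge in %d iterations (last objective change %.3g)",
      max_iter, utils::tail(diff(obj_trace), 1)))
  }
  coef_full <- numeric(p)
  coef_full[keep] <- core$beta / scl[keep]
  names(coef_full) <- colnames(X)
  list(coefficients = coef_full, n_iter = length(obj_trace) - 1L,
       objective = obj_trace, converged = TRUE)
}

#' Regularization path for the penalized Cox model
#'
#' Log-spaced sequence from the smallest lambda that zeroes every coefficient
#' (computed from the null-model score) down to `lambda_min_ratio` times it.
#'
#' @inheritParams penalized_cox_fit
#' @param nlambda Number of path points.
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @return Decreasing numeric vector of lambda values.
#' @export
cox_lambda_path <- function(X, time, event, l1_ratio = 0.1, nlambda = 30L,
                            lambda_min_ratio = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  dv <- cox_eta_derivs(numeric(n), time, as.logical(event))
  grad0 <- abs(crossprod(Xs, dv$g)) / n
  lambda_max <- max(grad0) / max(l1_ratio, 1e-3)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

#' Cross-validated choice of the Cox penalty strength
#'
#' k-fold cross-validation of the partial-likelihood deviance using the
#' Verweij-van Houwelingen construction: for each fold, the deviance
#' contribution is `-2 * (logpl(full data) - logpl(training fold))` at the
#' fold-trained coefficients, so tied survival times never form degenerate
#' risk sets in a held-out subset.
#'
#' @inheritParams penalized_cox_fit
#' @param nfolds Number of folds (default 5).
#' @param foldid Optional integer fold assignment per unit; when absent,
#'   folds are drawn from the current RNG stream.
#' @param lambda Optional lambda sequence; defaults to [cox_lambda_path()].
#' @return List with `lambda` (sequence), `cvm` (mean deviance), `cvsd`
#'   (its standard error over folds), `lambda_min`, `lambda_1se` (largest
#'   lambda with mean deviance within one standard error of the minimum),
#'   and `foldid`.
#' @export
cox_cv_lambda <- function(X, time, event, l1_ratio = 0.1, nfolds = 5L,
                          foldid = NULL, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  event <- as.logical(event)
  if (is.null(lambda)) lambda <- cox_lambda_path(X, time, event, l1_ratio)
  if (is.null(foldid)) {
    for (try in 1:50) {
      foldid <- sample(rep_len(seq_len(nfolds), n))
      ok <- all(vapply(seq_len(nfolds),
                       function(k) sum(event[foldid != k]) >= 1, logical(1)))
      if (ok) break
    }
  }
  dev <- matrix(0, nrow = nfolds, ncol = length(lambda))
  full_ll <- function(beta) cox_partial_loglik(as.numeric(X %*% beta), time, event)
  for (k in seq_len(nfolds)) {
    tr <- foldid != k
    warm <- NULL
    for (j in seq_along(lambda)) {
      fit <- penalized_cox_fit(X[tr, , drop = FALSE], time[tr], event[tr],
                               l1_ratio = l1_ratio, lambda = lambda[j],
                               beta_init = warm)
      b <- fit$coefficients
      warm <- b
      ll_tr <- cox_partial_loglik(as.numeric(X[tr, , drop = FALSE] %*% b),
                                  time[tr], event[tr])
      dev[k, j] <- -2 * (full_ll(b) - ll_tr)
    }
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, stats::sd) / sqrt(nfolds)
  imin <- which.min(cvm)
  within_1se <- which(cvm <= cvm[imin] + cvsd[imin])
  list(lambda = lambda, cvm = cvm, cvsd = cvsd,
       lambda_min = lambda[imin],
       lambda_1se = max(lambda[within_1se]), foldid = foldid)
}
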