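# Leave-one-out Cox elastic-net stability selection: train on all units but
# one, choose the penalty strength by inner cross-validated
# partial-likelihood deviance, record which candidate CpGs carry nonzero
# coefficients, keep those selected in more than half of the iterations,
# average their nonzero coefficients, and stratify by the median risk score.

#' Leave-one-out Cox elastic-net selection
#'
#' One iteration per unit: the model is trained on the remaining units with
#' elastic-net mixing `l1_ratio` and penalty strength chosen by inner k-fold
#' cross-validated partial-likelihood deviance on the training units; the
#' coefficient vector and the held-out unit's linear-predictor risk score
#' are recorded. Iterations that fail to converge are skipped and counted;
#' more than 20% skips is an error.
#'
#' @param X Numeric matrix, units x candidate CpGs (beta values), rownames
#'   are unit ids.
#' @param survival [survival_table()] covering every unit.
#' @param l1_ratio Elastic-net mixing (default 0.1, mostly ridge, keeping
#'   most candidates in the model).
#' @param inner_cv_folds Folds of the inner lambda cross-validation.
#' @param nlambda Lambda-path resolution of the inner search (default 20).
#' @param lambda_rule `"1se"` (default; the largest penalty within one
#'   standard error of the minimal cross-validated deviance, the
#'   conventional guard against selecting pure noise) or `"min"`.
#' @param seed Integer seed for the inner fold assignments.
#' @return List with `coefficients` (iterations x candidates matrix, one row
#'   per completed iteration, rownames = held-out unit), `heldout_scores`,
#'   `lambda` (chosen per iteration), and `skipped` (unit ids).
#' @export
loocv_selection <- function(X, survival, l1_ratio = 0.1, inner_cv_folds = 5L,
                            nlambda = 20L, lambda_rule = c("1se", "min"),
                            seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  # canonical unit order so results are invariant to input row permutation
  X <- X[order(rownames(X)), , drop = FALSE]
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 units")
  ix <- match(rownames(X), survival$unit_id)
  if (anyNA(ix)) stop("survival table must cover every unit")
  time <- survival$time_months[ix]
  event <- as.logical(survival$event[ix])
  if (sum(event) < 2L) stop("need at least 2 events")
  set.seed(seed)
  coefs <- matrix(NA_real_, n, ncol(X),
                  dimnames = list(rownames(X), colnames(X)))
  scores <- stats::setNames(rep(NA_real_, n), rownames(X))
  lambdas <- stats::setNames(rep(NA_real_, n), rownames(X))
  skipped <- character(0)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    res <- tryCatch({
      path <- cox_lambda_path(X[tr, , drop = FALSE], time[tr], event[tr],
                              l1_ratio, nlambda = nlambda)
      cv <- cox_cv_lambda(X[tr, , drop = FALSE], time[tr], event[tr],
                          l1_ratio, nfolds = inner_cv_folds, lambda = path)
      lam <- if (lambda_rule == "1se") cv$lambda_1se else cv$lambda_min
      fit <- penalized_cox_fit(X[tr, , drop = FALSE], time[tr], event[tr],
                               l1_ratio = l1_ratio, lambda = lam)
      list(b = fit$coefficients, lambda = lam)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, rownames(X)[i])
      next
    }
    coefs[i, ] <- res$b
    scores[i] <- sum(X[i, ] * res$b)
    lambdas[i] <- res$lambda
  }
  if (length(skipped) > 0.2 * n) {
    stop("more than 20% of LOOCV iterations failed to converge (",
         length(skipped), " of ", n, ")")
  }
  done <- !rownames(X) %in% skipped
  list(coefficients = coefs[done, , drop = FALSE],
       heldout_scores = scores[done], lambda = lambdas[done],
       skipped = skipped)
}

#' Build the final risk model from the LOOCV coefficient matrix
#'
#' Retains the candidates with nonzero coefficients in strictly more than
#' `frequency_threshold` of the iterations; each retained coefficient is the
#' mean over the iterations in which it was nonzero. The stratification
#' cutoff is the median linear-predictor risk score over all training units.
#'
#' @param coefficients Iterations x candidates matrix from
#'   [loocv_selection()].
#' @param X Training matrix (units x candidates).
#' @param survival Training survival table (kept alongside the model).
#' @param frequency_threshold Selection-frequency threshold (default 0.5,
#'   strict inequality).
#' @return Object of class `risk_model`: `probes`, `coefficients`, `cutoff`,
#'   `selection_frequency` (all candidates).
#' @export
build_final_model <- function(coefficients, X, survival,
                              frequency_threshold = 0.5) {
  freq <- colMeans(coefficients != 0)
  keep <- freq > frequency_threshold
  if (!any(keep)) stop("empty model: no candidate exceeds the selection-frequency threshold")
  coef <- vapply(which(keep), function(j) {
    v <- coefficients[, j]
    mean(v[v != 0])
  }, numeric(1))
  probes <- colnames(coefficients)[keep]
  scores <- as.numeric(X[, probes, drop = FALSE] %*% coef)
  structure(list(probes = probes,
                 coefficients = stats::setNames(coef, probes),
                 cutoff = stats::median(scores),
                 selection_frequency = freq),
            class = "risk_model")
}

#' Risk scores under a final model
#'
#' @param model A `risk_model`.
#' @param X Units x CpGs beta matrix covering the model probes.
#' @return Named numeric vector of linear-predictor risk scores.
#' @export
risk_score <- function(model, X) {
  miss <- setdiff(model$probes, colnames(X))
  if (length(miss)) stop("X lacks model probes: ", paste(miss, collapse = ", "))
  stats::setNames(as.numeric(X[, model$probes, drop = FALSE] %*%
                               model$coefficients), rownames(X))
}

#' Stratify units by the model cutoff and test group survival
#'
#' Units with risk score above (or equal to) the cutoff form the high-risk
#' group; Kaplan-Meier curves are estimated per group and the groups are
#' compared with the two-group log-rank test.
#'
#' @param model A `risk_model`.
#' @param X Units x CpGs beta matrix.
#' @param survival [survival_table()] covering every unit.
#' @return List with `groups` (data frame unit_id, score, risk_group), `km`
#'   (a `survival::survfit` object over the two groups), `logrank`
#'   (the [logrank_test()] result) and `p`.
#' @export
stratify_and_test <- function(model, X, survival) {
  scores <- risk_score(model, X)
  grp <- ifelse(scores >= model$cutoff, "high", "low")
  ix <- match(rownames(X), survival$unit_id)
  if (anyNA(ix)) stop("survival table must cover every unit")
  time <- survival$time_months[ix]
  event <- as.logical(survival$event[ix])
  lr <- tryCatch(logrank_test(time, event, grp), error = function(e) {
    stop("risk stratification degenerate (", conditionMessage(e),
         "); all units fell in one risk group?", call. = FALSE)
  })
  km <- survival::survfit(survival::Surv(time, event) ~ grp)
  list(groups = data.frame(unit_id = rownames(X), score = scores,
                           risk_group = grp, stringsAsFactors = FALSE),
       km = km, logrank = lr, p = lr$p)
}
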