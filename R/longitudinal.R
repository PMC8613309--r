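#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit written from first principles (the
#' Study-1 style analysis of treat refusal on infant temperament):
#' Newton-Raphson via IRLS, Wald z and p per coefficient from the inverse
#' observed information.  Convergence when the relative change in
#' log-likelihood falls below `tol`.
#'
#' Complete (quasi-)separation makes the MLE diverge; it is detected by
#' runaway coefficients / vanishing weights and raised as an error naming
#' the worst predictor rather than returning silently absurd estimates.
#'
#' @param outcome 0/1 (or logical) response vector containing both
#'   classes.
#' @param predictors Data frame or matrix of named predictors (an
#'   intercept is added automatically).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return A `logistic_fit` list: `coefficients`, `se`, `z`, `p_value`
#'   (named vectors), `loglik`, `iterations`, `converged`.
#' @export
fit_logistic <- function(outcome, predictors, tol = 1e-10, max_iter = 100L) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(y)) < 2) stop("outcome has a single class; fit undefined")
  X <- as.matrix(cbind(`(Intercept)` = 1, as.data.frame(predictors)))
  if (nrow(X) != length(y)) stop("outcome / predictor length mismatch")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient predictor matrix")
  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (!is.finite(ll) || max(abs(beta)) > 30) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop("complete or quasi-complete separation detected (predictor '",
           worst, "'); logistic MLE does not exist")
    }
    if (abs(ll - ll_old) < tol * (abs(ll) + tol)) { converged <- TRUE; break }
    ll_old <- ll
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    beta <- as.numeric(solve(XtWX, crossprod(X, w * z)))
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  zstat <- beta / se
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(zstat, colnames(X)),
    p_value = stats::setNames(2 * stats::pnorm(-abs(zstat)), colnames(X)),
    loglik = sum(y * log(mu) + (1 - y) * log1p(-mu)),
    iterations = it, converged = converged, n = length(y)),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value)
  cat(sprintf("logistic fit (n = %d, logLik = %.3f, %s)\n", x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  print(round(tab, 4))
  invisible(x)
}

#' Pearson chi-squared test of 2x2 stability
#'
#' Test-retest association between two paired dichotomous assessments:
#' Pearson's chi-squared on the 2x2 cross-tabulation with 1 degree of
#' freedom and no continuity correction by default (Yates optional).
#' With balanced margins and identical vectors the statistic equals n.
#'
#' @param assessA,assessB Paired 0/1 (or logical) vectors.
#' @param correct Apply the Yates continuity correction.
#' @return A `contingency_result` list: `table` (2x2 counts), `statistic`,
#'   `df` (= 1), `p_value`, `n`.
#' @export
stability_chi2 <- function(assessA, assessB, correct = FALSE) {
  a <- as.integer(as.logical(assessA))
  b <- as.integer(as.logical(assessB))
  if (length(a) != length(b)) stop("paired vectors required")
  if (anyNA(a) || anyNA(b)) stop("missing values in assessments")
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin (all-0 or all-1 assessment); chi-squared undefined")
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  dev <- abs(tab - E)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  structure(list(table = unclass(tab), statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 n = n, yates = correct),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 stability: chi2 = %.2f, df = 1, p = %.3g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  print(x$table)
  invisible(x)
}

#' Summarize treat-refusal records
#'
#' Descriptive summary of a refusal data set: refusal proportion by
#' temperament group, the all-or-nothing pattern (among first-trial
#' refusers, the percentage that retrieved any later treat), and the
#' consistency of the all-trials refusal outcome across consecutive
#' assessment pairs.
#'
#' @param records Data frame with columns `id`, `assessment`,
#'   `first_trial_refused`, `refused` and optionally `inhibited`.
#' @return List: `refusal_by_group` (data.frame), `first_refusers`,
#'   `later_retrievers`, `later_retrieval_pct`, `consistency_pct`.
#' @export
refusal_summary <- function(records) {
  stopifnot(nrow(records) > 0,
            all(c("id", "assessment", "first_trial_refused", "refused")
                %in% names(records)))
  first <- records[records$assessment == min(records$assessment), ]
  by_group <- if ("inhibited" %in% names(records)) {
    agg <- stats::aggregate(cbind(refused, first_trial_refused) ~ inhibited,
                            data = first, FUN = mean)
    agg
  } else data.frame(inhibited = NA,
                    refused = mean(first$refused),
                    first_trial_refused = mean(first$first_trial_refused))
  nref <- sum(first$first_trial_refused == 1)
  nretr <- sum(first$first_trial_refused == 1 & first$refused == 0)
  later_pct <- if (nref > 0) 100 * nretr / nref else NA_real_

  cons <- NA_real_
  assessments <- sort(unique(records$assessment))
  if (length(assessments) > 1) {
    pair_cons <- vapply(seq_len(length(assessments) - 1), function(k) {
      a <- records[records$assessment == assessments[k],
                   c("id", "refused")]
      b <- records[records$assessment == assessments[k + 1],
                   c("id", "refused")]
      m <- merge(a, b, by = "id")
      if (!nrow(m)) return(NA_real_)
      100 * mean(m$refused.x == m$refused.y)
    }, numeric(1))
    cons <- mean(pair_cons, na.rm = TRUE)
  }
  list(refusal_by_group = by_group,
       first_refusers = nref,
       later_retrievers = nretr,
       later_retrieval_pct = later_pct,
       consistency_pct = cons)
}
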