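#' Univariate animal-model REML
#'
#' Fits \eqn{y = X\beta + a + e} with \eqn{a \sim N(0, \sigma^2_a A)} and
#' \eqn{e \sim N(0, \sigma^2_e I)} by restricted maximum likelihood.  The
#' relationship matrix is eigendecomposed once (\eqn{A = U D U'}); on the
#' rotated data the covariance is diagonal for any variance ratio, so the
#' REML criterion is profiled down to a one-dimensional search over
#' \eqn{h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e) \in [0,1]} with the total
#' variance profiled out analytically.
#'
#' The standard error of \eqn{h^2} comes from the numerical curvature of
#' the profile REML log-likelihood at the optimum; the p-value against
#' \eqn{\sigma^2_a = 0} uses the likelihood-ratio statistic with the 50:50
#' \eqn{\chi^2_0 : \chi^2_1} boundary mixture, so a likelihood ratio of
#' zero yields p = 0.5.
#'
#' @param y Numeric response (inverse-normal transform upstream when
#'   analyzing temperament scores); NA entries (with matching rows of X/A)
#'   are dropped.
#' @param X Fixed-effect design matrix including the intercept (default:
#'   intercept only).  Supply e.g. `model.matrix(~ sex, data)` to control
#'   for sex.
#' @param A Additive relationship (or kinship) matrix aligned with `y`.
#' @param Aeig Optional precomputed `eigen(A, symmetric = TRUE)`, reused
#'   across replicate fits on the same pedigree.
#' @param se Compute the curvature-based standard error (default TRUE).
#' @param tol Relative convergence tolerance of the 1-D search.
#' @return A `vc_fit` list: `sigma2_a`, `sigma2_e`, `h2`, `se_h2`,
#'   `lrt_statistic`, `p_value`, `beta` (fixed effects), `loglik`,
#'   `loglik_null`, `status` ("converged", "boundary" or
#'   "unidentifiable"), `n`, `df`.
#' @export
reml_univariate <- function(y, X = NULL, A, Aeig = NULL, se = TRUE,
                            tol = 1e-10) {
  keep <- is.finite(y)
  if (!all(keep)) {
    y <- y[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    A <- A[keep, keep, drop = FALSE]
    Aeig <- NULL
  }
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient fixed-effect design")
  if (n <= p + 1) stop("too few observations")
  if (is.null(Aeig)) {
    if (nrow(A) != n) stop("A dimension mismatch")
    Aeig <- eigen(A, symmetric = TRUE)
  }
  d <- Aeig$values
  if (min(d) < -1e-6 * max(abs(d))) stop("relationship matrix is not PSD")
  d <- pmax(d, 0)
  U <- Aeig$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)

  ll <- function(h2) reml_profile_ll(h2, ys, Xs, d, n, p)$ll
  opt <- stats::optimize(ll, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, 1 - 1e-6)
  lls <- c(opt$objective, ll(0), ll(1 - 1e-6))
  best <- which.max(lls)
  h2 <- cand[best]
  llmax <- lls[best]
  fit <- reml_profile_ll(h2, ys, Xs, d, n, p)
  ll0 <- lls[2]

  status <- "converged"
  if (max(lls) - min(ll(0.25), ll(0.75)) < 1e-8) status <- "unidentifiable"
  else if (h2 <= 1e-4 || h2 >= 1 - 1e-3) status <- "boundary"

  lrt <- max(0, 2 * (llmax - ll0))
  p_value <- if (lrt <= 0) 0.5 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  se_h2 <- NA_real_
  if (se && status == "converged") {
    del <- min(1e-3, h2 / 2, (1 - h2) / 2)
    curv <- (ll(h2 + del) - 2 * llmax + ll(h2 - del)) / del^2
    if (is.finite(curv) && curv < 0) se_h2 <- sqrt(-1 / curv)
  }

  structure(list(
    sigma2_a = h2 * fit$sigma2, sigma2_e = (1 - h2) * fit$sigma2,
    h2 = h2, se_h2 = se_h2, lrt_statistic = lrt, p_value = p_value,
    beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
    loglik = llmax, loglik_null = ll0, status = status,
    n = n, df = n - p), class = "vc_fit")
}

# Profile REML log-likelihood at a given variance ratio h2, on rotated
# data.  Returns the full REML log-likelihood (constants included) with
# the total variance profiled out.
reml_profile_ll <- function(h2, ys, Xs, d, n, p) {
  w <- 1 / (h2 * d + (1 - h2))
  if (any(!is.finite(w))) return(list(ll = -Inf))
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r2 <- sum(ys^2 * w) - sum(XtWy * beta)
  if (r2 <= 0) return(list(ll = -Inf))
  sigma2 <- r2 / (n - p)
  ll <- -0.5 * (-sum(log(w)) + 2 * sum(log(diag(ch))) +
                  (n - p) * log(sigma2) + (n - p) +
                  (n - p) * log(2 * pi))
  list(ll = ll, sigma2 = sigma2, beta = beta)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("animal model REML (n = %d): h2 = %.4f (se %.4f)\n",
              x$n, x$h2, x$se_h2))
  cat(sprintf("  sigma2_a = %.4f  sigma2_e = %.4f  LRT = %.3f  p = %.3g  [%s]\n",
              x$sigma2_a, x$sigma2_e, x$lrt_statistic, x$p_value, x$status))
  invisible(x)
}

#' Bivariate animal-model REML (genetic correlation)
#'
#' Fits the two-trait animal model with genetic covariance
#' \eqn{\rho_g \sigma_{a1} \sigma_{a2}} and residual covariance
#' \eqn{\rho_e \sigma_{e1} \sigma_{e2}}.  Both traits share the
#' relationship matrix, so after rotating each trait by the eigenvectors
#' of A the 2n-dimensional covariance splits into n independent 2x2
#' blocks and every REML evaluation is O(n).  The six parameters are
#' maximized on an unconstrained scale (log variances, atanh
#' correlations) by Nelder-Mead with a restart.
#'
#' The p-value for \eqn{\rho_g = 0} is the likelihood-ratio test against
#' the model with the genetic covariance constrained to zero
#' (\eqn{\chi^2_1}); `se_rho_g` comes from the inverse numerical Hessian
#' with a delta-method back-transform.
#'
#' @param y1,y2 Trait vectors on the same animals; animals missing either
#'   trait are dropped.
#' @param X Fixed-effect design (intercept default).
#' @param A Relationship matrix.
#' @param Aeig Optional precomputed eigendecomposition of A.
#' @param test Compute the rho_g = 0 LRT p-value (default TRUE).
#' @param se Compute se_rho_g from the numerical Hessian (default TRUE).
#' @return A `rho_g_fit` list: `rho_g`, `rho_e`, `se_rho_g`, per-trait
#'   variance components, `lrt_statistic`, `p_value`, `loglik`, `status`.
#' @export
reml_bivariate <- function(y1, y2, X = NULL, A, Aeig = NULL, test = TRUE,
                           se = TRUE) {
  keep <- is.finite(y1) & is.finite(y2)
  if (!all(keep)) {
    y1 <- y1[keep]; y2 <- y2[keep]
    if (!is.null(X)) X <- X[keep, , drop = FALSE]
    A <- A[keep, keep, drop = FALSE]
    Aeig <- NULL
  }
  n <- length(y1)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  if (stats::var(y1) == 0 || stats::var(y2) == 0)
    stop("degenerate (zero-variance) trait")
  if (is.null(Aeig)) Aeig <- eigen(A, symmetric = TRUE)
  d <- pmax(Aeig$values, 0)
  U <- Aeig$vectors
  y1s <- as.numeric(crossprod(U, y1))
  y2s <- as.numeric(crossprod(U, y2))
  Xs <- crossprod(U, X)

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  start <- c(log(0.4 * v1), log(0.4 * v2), 0, log(0.6 * v1), log(0.6 * v2), 0)
  nll <- function(th) -biv_ll(th, y1s, y2s, Xs, d, n, p)
  o <- stats::optim(start, nll, method = "Nelder-Mead",
                    control = list(maxit = 3000, reltol = 1e-12))
  o2 <- stats::optim(o$par, nll, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-12))
  if (o2$value < o$value) o <- o2
  th <- o$par
  ll1 <- -o$value
  pars <- biv_par(th)
  status <- if (o$convergence == 0 || o2$convergence == 0) "converged"
            else "not_converged"
  if (abs(pars$rho_g) > 0.9999 || abs(pars$rho_e) > 0.9999)
    status <- paste0(status, "_boundary")

  lrt <- NA_real_; p_value <- NA_real_; ll0 <- NA_real_
  if (test) {
    nll0 <- function(th5) -biv_ll(c(th5[1:2], 0, th5[3:4], th5[5]),
                                  y1s, y2s, Xs, d, n, p, fix_rho_g = TRUE)
    s0 <- th[c(1, 2, 4, 5, 6)]
    c0 <- stats::optim(s0, nll0, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-12))
    ll0 <- -c0$value
    lrt <- max(0, 2 * (ll1 - ll0))
    p_value <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }

  se_rho_g <- NA_real_
  if (se) {
    H <- num_hessian(function(t) biv_ll(t, y1s, y2s, Xs, d, n, p), th)
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && V[3, 3] > 0)
      se_rho_g <- (1 - pars$rho_g^2) * sqrt(V[3, 3])
  }

  structure(list(
    rho_g = pars$rho_g, rho_e = pars$rho_e, se_rho_g = se_rho_g,
    sigma2_a = c(trait1 = pars$s2a1, trait2 = pars$s2a2),
    sigma2_e = c(trait1 = pars$s2e1, trait2 = pars$s2e2),
    h2 = c(trait1 = pars$s2a1 / (pars$s2a1 + pars$s2e1),
           trait2 = pars$s2a2 / (pars$s2a2 + pars$s2e2)),
    lrt_statistic = lrt, p_value = p_value,
    loglik = ll1, loglik_null = ll0, status = status, n = n),
    class = "rho_g_fit")
}

biv_par <- function(th) {
  list(s2a1 = exp(th[1]), s2a2 = exp(th[2]), rho_g = tanh(th[3]),
       s2e1 = exp(th[4]), s2e2 = exp(th[5]), rho_e = tanh(th[6]))
}

# REML log-likelihood of the rotated bivariate model; O(n) per call.
biv_ll <- function(th, y1s, y2s, Xs, d, n, p, fix_rho_g = FALSE) {
  pr <- biv_par(th)
  if (fix_rho_g) pr$rho_g <- 0
  ca <- pr$rho_g * sqrt(pr$s2a1 * pr$s2a2)
  ce <- pr$rho_e * sqrt(pr$s2e1 * pr$s2e2)
  v11 <- pr$s2a1 * d + pr$s2e1
  v22 <- pr$s2a2 * d + pr$s2e2
  v12 <- ca * d + ce
  det_i <- v11 * v22 - v12^2
  if (any(det_i <= 0) || any(v11 <= 0)) return(-Inf)
  a <- v22 / det_i; b <- -v12 / det_i; cc <- v11 / det_i
  M11 <- crossprod(Xs, Xs * a)
  M12 <- crossprod(Xs, Xs * b)
  M22 <- crossprod(Xs, Xs * cc)
  M <- rbind(cbind(M11, M12), cbind(M12, M22))
  u <- c(crossprod(Xs, a * y1s + b * y2s),
         crossprod(Xs, b * y1s + cc * y2s))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  sol <- backsolve(ch, forwardsolve(t(ch), u))
  qform <- sum(a * y1s^2 + 2 * b * y1s * y2s + cc * y2s^2) - sum(u * sol)
  if (!is.finite(qform)) return(-Inf)
  -0.5 * (sum(log(det_i)) + 2 * sum(log(diag(ch))) + qform +
            (2 * n - 2 * p) * log(2 * pi))
}

num_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- eps; ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * eps^2)
  }
  H
}

#' @export
print.rho_g_fit <- function(x, ...) {
  cat(sprintf("bivariate animal model REML (n = %d): rho_g = %.3f (se %.3f)\n",
              x$n, x$rho_g, x$se_rho_g))
  cat(sprintf("  rho_e = %.3f  h2 = %.3f / %.3f  LRT p = %.3g  [%s]\n",
              x$rho_e, x$h2[1], x$h2[2], x$p_value, x$status))
  invisible(x)
}

#' Heritability and genetic-correlation summary table
#'
#' Collects univariate fits for the inhibited-temperament composite and
#' its four latent factors together with the pairwise genetic
#' correlations into a single report: one h2 +/- SE row per variable and
#' a symmetric rho_g matrix with unit diagonal.  Non-converged cells are
#' marked NA rather than reported silently.
#'
#' @param univariate Named list of `vc_fit` objects.
#' @param bivariate Named list of `rho_g_fit` objects, names of the form
#'   `"traitA|traitB"` matching the univariate names.
#' @return List with `h2_table` (data.frame: trait, h2, se, p, status) and
#'   `rho_g_matrix`.
#' @export
heritability_report <- function(univariate, bivariate = list()) {
  traits <- names(univariate)
  h2_table <- do.call(rbind, lapply(traits, function(tr) {
    f <- univariate[[tr]]
    ok <- f$status %in% c("converged", "boundary")
    data.frame(trait = tr,
               h2 = if (ok) f$h2 else NA_real_,
               se = f$se_h2,
               p_value = if (ok) f$p_value else NA_real_,
               status = f$status, stringsAsFactors = FALSE)
  }))
  R <- matrix(NA_real_, length(traits), length(traits),
              dimnames = list(traits, traits))
  diag(R) <- 1
  for (nm in names(bivariate)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% traits))
      stop("bivariate fit name '", nm, "' does not match traits")
    f <- bivariate[[nm]]
    val <- if (startsWith(f$status, "converged")) f$rho_g else NA_real_
    R[pair[1], pair[2]] <- R[pair[2], pair[1]] <- val
  }
  list(h2_table = h2_table, rho_g_matrix = R)
}
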