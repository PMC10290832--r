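#' Maximum likelihood fit of a two-parameter Weibull distribution
#'
#' Fits the Weibull distribution with scale \eqn{c} and shape \eqn{k},
#' density \eqn{f(x) = (k/c)(x/c)^{k-1} \exp[-(x/c)^k]}, by maximum
#' likelihood.  The shape MLE is the root of the profile score
#' \deqn{1/\hat k - \sum x^{\hat k}\log x / \sum x^{\hat k} + \overline{\log x} = 0,}
#' found by a bracketed, safeguarded Newton iteration, and the scale MLE is
#' the profile expression \eqn{\hat c = (\sum x^{\hat k}/n)^{1/\hat k}}.
#'
#' @param x numeric vector of strictly positive observations, length >= 2,
#'   not all identical.
#' @param group optional label attached to the fit (used in error messages
#'   and printed output).
#' @return an object of class `"weibull_fit"`: a list with elements
#'   `c_hat`, `k_hat`, `n`, `loglik` and `group`.
#' @examples
#' x <- qweibull(ppoints(40), shape = 2, scale = 1.5)
#' fit_weibull_mle(x)
#' @export
fit_weibull_mle <- function(x, group = NULL) {
  label <- if (is.null(group)) "sample" else sprintf("group '%s'", group)
  if (!is.numeric(x) || length(x) < 2L)
    domain_error(sprintf("%s: at least 2 numeric observations are required", label))
  if (any(!is.finite(x)) || any(x <= 0))
    domain_error(sprintf("%s: all observations must be finite and strictly positive", label))
  if (diff(range(x)) == 0)
    estimation_error(sprintf("%s: all observations identical; the shape MLE diverges", label))
  lx <- log(x)
  k_hat <- solve_shape_rows(matrix(lx, nrow = 1L))
  if (is.na(k_hat))
    estimation_error(sprintf("%s: profile score root could not be bracketed", label))
  c_hat <- profile_scale(x, k_hat)
  n <- length(x)
  loglik <- n * log(k_hat) - n * k_hat * log(c_hat) +
    (k_hat - 1) * sum(lx) - sum((x / c_hat)^k_hat)
  structure(
    list(c_hat = c_hat, k_hat = k_hat, n = n, loglik = loglik, group = group),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, digits = 4L, ...) {
  hdr <- if (is.null(x$group)) "Weibull MLE fit" else sprintf("Weibull MLE fit (%s)", x$group)
  cat(hdr, "\n", sep = "")
  cat(sprintf("  n = %d, scale = %.*f, shape = %.*f, logLik = %.*f\n",
              x$n, digits, x$c_hat, digits, x$k_hat, digits, x$loglik))
  cat(sprintf("  mean = %.*f\n", digits, weibull_mean(x$c_hat, x$k_hat)))
  invisible(x)
}

#' Mean of a Weibull distribution
#'
#' Returns \eqn{\mu = c \, \Gamma(1 + 1/k)} for scale `c` and shape `k`.
#'
#' @param c positive scale parameter(s).
#' @param k positive shape parameter(s).
#' @return the Weibull mean(s), recycled over `c` and `k`.
#' @examples
#' weibull_mean(1, 2)   # sqrt(pi)/2
#' @export
weibull_mean <- function(c, k) {
  if (any(!is.finite(c)) || any(!is.finite(k)) || any(c <= 0) || any(k <= 0))
    domain_error("scale and shape must be finite and strictly positive")
  c * gamma(1 + 1 / k)
}

#' Observed information matrix of a Weibull fit
#'
#' The observed information is the negative Hessian of the Weibull
#' log-likelihood in (shape, scale), evaluated at the MLEs.  Its inverse
#' estimates `var(k_hat)`, `var(c_hat)` and their covariance.
#'
#' @param fit a [fit_weibull_mle()] result.
#' @param x the numeric sample the fit was produced from.
#' @return a symmetric 2x2 matrix with dimnames `c("k", "c")`.
#' @export
observed_information <- function(fit, x) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (length(x) != fit$n)
    domain_error("sample length does not match the fit")
  k <- fit$k_hat; cc <- fit$c_hat; n <- fit$n
  lr <- log(x / cc)
  t <- (x / cc)^k
  s <- sum(t)
  I_kk <- n / k^2 + sum(t * lr^2)
  I_kc <- -((s - n) / cc + (k / cc) * sum(t * lr))
  I_cc <- (k / cc^2) * (s - n) + (k^2 / cc^2) * s
  m <- matrix(c(I_kk, I_kc, I_kc, I_cc), 2L, 2L,
              dimnames = list(c("k", "c"), c("k", "c")))
  if (!is.finite(determinant(m)$modulus) || det(m) <= 0)
    estimation_error("observed information matrix is singular")
  m
}

#' Expected (Fisher) information matrix of the Weibull MLEs
#'
#' Closed form for sample size `n` at parameters (`c`, `k`), in (shape,
#' scale) order.  Used to weight pivotal and posterior draws, where the
#' information must be a function of the substituted parameter values only.
#'
#' @param c positive scale parameter.
#' @param k positive shape parameter.
#' @param n sample size.
#' @return a symmetric 2x2 matrix with dimnames `c("k", "c")`.
#' @export
expected_information <- function(c, k, n) {
  if (c <= 0 || k <= 0 || n < 1)
    domain_error("c, k must be positive and n >= 1")
  om <- 1 - EULER_GAMMA
  a <- (om^2 + pi^2 / 6) / k^2
  b <- -om / c
  d <- k^2 / c^2
  n * matrix(c(a, b, b, d), 2L, 2L,
             dimnames = list(c("k", "c"), c("k", "c")))
}

#' Delta-method variance of the estimated Weibull mean
#'
#' Propagates the MLE covariance through \eqn{\mu(c,k) = c\,\Gamma(1+1/k)}
#' with the analytic partials \eqn{\partial\mu/\partial c = \Gamma(1+1/k)}
#' and \eqn{\partial\mu/\partial k = -(c/k^2)\Gamma(1+1/k)\psi(1+1/k)},
#' where \eqn{\psi} is the digamma function.
#'
#' @param fit a [fit_weibull_mle()] result.
#' @param info_inverse inverse information matrix in (shape, scale) order,
#'   e.g. `solve(observed_information(fit, x))`.
#' @return the estimated variance of the fitted mean (positive scalar).
#' @export
delta_variance <- function(fit, info_inverse) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!is.matrix(info_inverse) || any(dim(info_inverse) != 2L))
    domain_error("info_inverse must be a 2x2 matrix in (k, c) order")
  delta_variance_entries(fit$c_hat, fit$k_hat,
                         var_k = info_inverse[1L, 1L],
                         var_c = info_inverse[2L, 2L],
                         cov_kc = info_inverse[1L, 2L])
}

#' Point estimate of a group mean with its delta-method variance
#'
#' Convenience wrapper: fits the Weibull MLEs, computes the fitted mean and
#' its delta-method variance from the observed information.
#'
#' @param x numeric vector of strictly positive observations.
#' @param group optional label.
#' @return a list of class `"weibull_mean_estimate"` with elements `mu_hat`,
#'   `var_hat`, `info_inverse` and `fit`.
#' @export
mean_estimate <- function(x, group = NULL) {
  fit <- fit_weibull_mle(x, group = group)
  info_inv <- solve(observed_information(fit, x))
  mu_hat <- weibull_mean(fit$c_hat, fit$k_hat)
  var_hat <- delta_variance(fit, info_inv)
  if (!is.finite(var_hat) || var_hat <= 0)
    estimation_error(sprintf("non-positive variance estimate for %s",
                             if (is.null(group)) "sample" else group))
  structure(list(mu_hat = mu_hat, var_hat = var_hat,
                 info_inverse = info_inv, fit = fit, group = group),
            class = "weibull_mean_estimate")
}

#' Inverse-variance-weighted common mean
#'
#' Pools per-group mean estimates by inverse-variance weighting:
#' \deqn{\hat\mu = \sum_i \hat\mu_i/\widehat{var}(\hat\mu_i) \Big/
#'       \sum_i 1/\widehat{var}(\hat\mu_i).}
#'
#' @param estimates a list of [mean_estimate()] objects, or a numeric vector
#'   of means (then `variances` is required).
#' @param variances numeric vector of positive variances, matching
#'   `estimates` when the latter is a numeric vector.
#' @return a list of class `"weibull_common_mean"` with elements
#'   `mu_pooled`, `weights` (summing to 1) and `p`.
#' @export
pool_common_mean <- function(estimates, variances = NULL) {
  if (is.list(estimates) && length(estimates) > 0 &&
      inherits(estimates[[1L]], "weibull_mean_estimate")) {
    mu <- vapply(estimates, `[[`, numeric(1L), "mu_hat")
    v <- vapply(estimates, `[[`, numeric(1L), "var_hat")
  } else {
    mu <- as.numeric(estimates)
    v <- as.numeric(variances)
  }
  if (length(mu) == 0L) domain_error("no estimates to pool")
  if (length(v) != length(mu) || any(!is.finite(v)) || any(v <= 0))
    domain_error("each estimate needs a positive variance")
  w <- (1 / v) / sum(1 / v)
  structure(list(mu_pooled = sum(w * mu), weights = w, p = length(mu)),
            class = "weibull_common_mean")
}

#' @export
print.weibull_common_mean <- function(x, digits = 4L, ...) {
  cat(sprintf("Common mean of %d groups: %.*f\n", x$p, digits, x$mu_pooled))
  cat("  weights:", paste(formatC(x$weights, digits = 3L, format = "f"), collapse = " "), "\n")
  invisible(x)
}
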