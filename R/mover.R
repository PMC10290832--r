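# Adjusted MOVER (method of variance estimates recovery) interval for the
# common Weibull mean.  Per-group log-scale Wald limits are recovered into
# variance estimates at the limits, and recombined:
#   L = mu_pooled - sqrt(1 / sum(1/(mu_i - l_i)^2))
#   U = mu_pooled + sqrt(1 / sum(1/(u_i - mu_i)^2))
# Fully deterministic.

#' Log-scale Wald interval for a positive mean
#'
#' \eqn{[\exp(\log\hat\mu \mp z_{\alpha/2}\sqrt{\widehat{var}(\log\hat\mu)})]}
#' with \eqn{\widehat{var}(\log\hat\mu) = \widehat{var}(\hat\mu)/\hat\mu^2}
#' (delta method on the log scale).  Both endpoints are positive and
#' \eqn{\hat\mu} lies strictly inside for positive variance.
#'
#' @param mu_hat positive point estimate.
#' @param var_mu positive variance of `mu_hat` (`0` is allowed and collapses
#'   the interval onto `mu_hat`).
#' @param level confidence level in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
wald_log_interval <- function(mu_hat, var_mu, level = 0.95) {
  if (any(mu_hat <= 0) || any(var_mu < 0))
    domain_error("mu_hat must be positive and var_mu non-negative")
  if (level <= 0 || level >= 1) domain_error("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(var_mu) / mu_hat
  c(mu_hat * exp(-half), mu_hat * exp(half))
}

#' Per-group MOVER components
#'
#' The per-group Wald limits and the variance estimates recovered from them:
#' \eqn{\hat V(\hat\mu_{l_i}) = (\hat\mu_i - l_i)^2/z^2},
#' \eqn{\hat V(\hat\mu_{u_i}) = (u_i - \hat\mu_i)^2/z^2}, together with their
#' symmetrized large-sample average `v_w`.  Exposed for inspection; the
#' interval itself uses the recovered variances directly.
#'
#' @param estimates list of [mean_estimate()] objects.
#' @param level confidence level.
#' @return a data frame with one row per group: `group`, `mu_hat`, `l`, `u`,
#'   `v_l`, `v_u`, `v_w` and `z`.
#' @export
mover_components <- function(estimates, level = 0.95) {
  mu <- vapply(estimates, `[[`, numeric(1L), "mu_hat")
  v <- vapply(estimates, `[[`, numeric(1L), "var_hat")
  z <- stats::qnorm(1 - (1 - level) / 2)
  lim <- mapply(function(m, vv) wald_log_interval(m, vv, level), mu, v)
  l <- lim[1L, ]; u <- lim[2L, ]
  v_l <- (mu - l)^2 / z^2
  v_u <- (u - mu)^2 / z^2
  groups <- vapply(seq_along(estimates), function(i) {
    g <- estimates[[i]]$group
    if (is.null(g)) sprintf("group%d", i) else g
  }, character(1L))
  data.frame(group = groups, mu_hat = mu, l = l, u = u,
             v_l = v_l, v_u = v_u, v_w = (v_l + v_u) / 2, z = z)
}

#' Adjusted MOVER interval for the common mean
#'
#' @param samples a named list of positive numeric vectors, a single numeric
#'   vector, a `group`/`value` data frame, or a list of [mean_estimate()]
#'   objects.
#' @param level confidence level in (0, 1).
#' @return a [new_interval()] object with method `"adjusted_mover"`.
#' @examples
#' wind <- surat_thani_wind()
#' adjusted_mover_interval(wind, level = 0.95)
#' @export
adjusted_mover_interval <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) domain_error("level must be in (0, 1)")
  estimates <- if (is.list(samples) && length(samples) > 0 &&
                   inherits(samples[[1L]], "weibull_mean_estimate")) {
    samples
  } else {
    samples <- as_sample_list(samples)
    mapply(mean_estimate, samples, names(samples), SIMPLIFY = FALSE)
  }
  comp <- mover_components(estimates, level)
  pooled <- pool_common_mean(estimates)$mu_pooled
  L <- pooled - sqrt(1 / sum(1 / (comp$mu_hat - comp$l)^2))
  U <- pooled + sqrt(1 / sum(1 / (comp$u - comp$mu_hat)^2))
  out <- new_interval(L, U, level, "adjusted_mover")
  attr(out, "mu_pooled") <- pooled
  out
}
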