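# Generalized confidence interval for the common Weibull mean.
#
# For each group with observed MLEs (c0, k0) and size n, one pivotal draw
# refits a fresh Weibull(1,1) sample of size n to (c*, k*) and forms
#   R_k  = k0 / k*
#   R_c  = (1/c*)^(k*/k0) * c0
#   R_mu = R_c * gamma(1 + 1/R_k)
# The draws are pooled across groups with weights 1/R_var, where R_var is the
# delta-method variance of the mean with the closed-form expected information
# evaluated at (R_c, R_k) and the group's n — a function of pivotal
# quantities only.  Empirical quantiles of the pooled draws give the
# interval.

#' Generalized pivotal quantity draws for the common Weibull mean
#'
#' Generates `m` joint pivotal draws for a set of groups.  Weibull(1,1)
#' star samples (standard exponentials) are generated by inverse-CDF from
#' uniforms, so a single seeded stream determines every draw.
#'
#' @param samples a named list of positive numeric vectors (one per group),
#'   a single numeric vector, or a `group`/`value` data frame.
#' @param m number of pivotal draws (>= 2).
#' @param seed optional integer seed; when given, results are reproducible
#'   and the caller's RNG state is untouched.
#' @param max_retries refit attempts allowed per draw before aborting.
#' @return a list with matrices `r_k`, `r_c`, `r_mu`, `r_var` (m x p), the
#'   pooled vector `r_mu_common` (length m), the per-group fits, and the
#'   total `retries` used to replace degenerate star samples.
#' @export
gpq_draws <- function(samples, m = 2500L, seed = NULL, max_retries = 100L) {
  samples <- as_sample_list(samples)
  if (m < 2L) domain_error("m must be at least 2")
  fits <- mapply(fit_weibull_mle, samples, names(samples), SIMPLIFY = FALSE)
  with_local_seed(seed, function() {
    p <- length(samples)
    r_k <- r_c <- r_mu <- r_var <- matrix(NA_real_, m, p,
                                          dimnames = list(NULL, names(samples)))
    retries <- 0L
    for (i in seq_len(p)) {
      n <- fits[[i]]$n
      k0 <- fits[[i]]$k_hat
      c0 <- fits[[i]]$c_hat
      lX <- log(-log1p(-matrix(stats::runif(m * n), m, n)))  # log Exp(1)
      ks <- solve_shape_rows(lX)
      bad <- which(is.na(ks))
      tries <- 0L
      while (length(bad) > 0L && tries < max_retries) {
        tries <- tries + 1L
        retries <- retries + length(bad)
        lX[bad, ] <- log(-log1p(-stats::runif(length(bad) * n)))
        ks[bad] <- solve_shape_rows(lX[bad, , drop = FALSE])
        bad <- which(is.na(ks))
      }
      if (length(bad) > 0L)
        estimation_error(sprintf("group '%s': star-sample refit failed beyond the retry budget",
                                 names(samples)[i]))
      cs <- profile_scale_rows(lX, ks)
      r_k[, i] <- k0 / ks
      r_c[, i] <- (1 / cs)^(ks / k0) * c0
      r_mu[, i] <- r_c[, i] * gamma(1 + 1 / r_k[, i])
      r_var[, i] <- delta_variance_expected(r_c[, i], r_k[, i], n)
    }
    w <- 1 / r_var
    r_mu_common <- rowSums(r_mu * w) / rowSums(w)
    list(r_k = r_k, r_c = r_c, r_mu = r_mu, r_var = r_var,
         r_mu_common = r_mu_common, fits = fits, retries = retries)
  })
}

#' Generalized confidence interval for the common mean
#'
#' The equal-tailed empirical quantiles (linear interpolation between order
#' statistics, `type = 7`) of the pooled pivotal draws.
#'
#' @inheritParams gpq_draws
#' @param level confidence level in (0, 1).
#' @return a [new_interval()] object with method `"gci"`; the pivotal draw
#'   count is attached as attribute `"m"`.
#' @examples
#' wind <- surat_thani_wind()
#' gci_interval(wind, level = 0.95, m = 500, seed = 1)
#' @export
gci_interval <- function(samples, level = 0.95, m = 2500L, seed = NULL) {
  if (level <= 0 || level >= 1) domain_error("level must be in (0, 1)")
  draws <- gpq_draws(samples, m = m, seed = seed)
  alpha <- 1 - level
  q <- stats::quantile(draws$r_mu_common, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  out <- new_interval(q[1L], q[2L], level, "gci")
  attr(out, "m") <- m
  attr(out, "retries") <- draws$retries
  out
}
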