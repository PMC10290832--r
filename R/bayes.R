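# Bayesian machinery for the common Weibull mean.
#
# Each group's Weibull likelihood is reparameterized with c' = (1/c)^k,
#   f(x; c', k) = c' k x^(k-1) exp(-c' x^k),
# under independent gamma priors k ~ gamma(v1, z1), c' ~ gamma(v2, z2).
# The c' conditional is conjugate, gamma(n + v2, z2 + sum x^k); the k
# conditional has no closed form and is updated by random-walk Metropolis.
# Group chains are pooled iteration-wise by inverse delta-method variance,
# and equitailed / highest-posterior-density intervals are read off the
# pooled draws.

#' Gamma prior hyperparameters for the Weibull shape and transformed scale
#'
#' @param v1,z1 shape and rate of the gamma prior on the shape `k`.
#' @param v2,z2 shape and rate of the gamma prior on `c' = (1/c)^k`.
#'   Defaults are diffuse proper priors.
#' @return a list of class `"weibull_gamma_prior"`.
#' @export
gamma_prior <- function(v1 = 1e-4, z1 = 1e-4, v2 = 1e-4, z2 = 1e-4) {
  if (any(c(v1, z1, v2, z2) <= 0))
    domain_error("all four hyperparameters must be positive")
  structure(list(v1 = v1, z1 = z1, v2 = v2, z2 = z2),
            class = "weibull_gamma_prior")
}

#' Log unnormalized conditional posterior of the Weibull shape
#'
#' \eqn{\log \pi(k \mid c', x) = (n + v_1 - 1)\log k + (k-1)\sum\log x_j
#'   - z_1 k - c' \sum x_j^k} up to an additive constant (the product of the
#' full likelihood and the gamma prior on `k`).  Returns `-Inf` for
#' `k <= 0`.  Vectorized over `k`.
#'
#' @param k shape value(s) at which to evaluate.
#' @param cprime positive transformed scale `c' = (1/c)^k`.
#' @param x positive sample (may be empty, leaving the prior only).
#' @param prior a [gamma_prior()].
#' @return log density value(s) up to a constant.
#' @export
log_unnormalized_posterior_k <- function(k, cprime, x, prior = gamma_prior()) {
  if (cprime <= 0) domain_error("cprime must be positive")
  n <- length(x)
  slx <- if (n > 0L) sum(log(x)) else 0
  out <- rep(-Inf, length(k))
  ok <- is.finite(k) & k > 0
  kk <- k[ok]
  sxk <- if (n > 0L) vapply(kk, function(ki) sum(x^ki), numeric(1L)) else 0
  out[ok] <- (n + prior$v1 - 1) * log(kk) + (kk - 1) * slx -
    prior$z1 * kk - cprime * sxk
  out
}

#' Draw from the conjugate conditional of the transformed scale
#'
#' One draw from \eqn{c' \mid k, x \sim \mathrm{gamma}(n + v_2,\;
#' z_2 + \sum x_j^k)} (shape/rate).
#'
#' @inheritParams log_unnormalized_posterior_k
#' @export
sample_cprime <- function(k, x, prior = gamma_prior()) {
  if (k <= 0) domain_error("k must be positive")
  stats::rgamma(1L, shape = length(x) + prior$v2, rate = prior$z2 + sum(x^k))
}

#' One random-walk Metropolis update of the shape
#'
#' Proposes \eqn{\tilde k = k + \varepsilon}, \eqn{\varepsilon \sim
#' N(0, \sigma^2)}, and accepts with probability \eqn{\min(1, A_k)} where
#' \eqn{\log A_k} is the difference of [log_unnormalized_posterior_k()] at
#' the proposal and the current point.  Non-positive proposals have zero
#' posterior mass and are always rejected.
#'
#' @param k_prev current shape value (positive).
#' @param cprime current transformed scale (positive).
#' @param x positive sample.
#' @param prior a [gamma_prior()].
#' @param sigma positive proposal standard deviation.
#' @return list with `k` (new state), `accepted` (logical) and `proposal`.
#' @export
rwm_update_k <- function(k_prev, cprime, x, prior = gamma_prior(), sigma) {
  if (k_prev <= 0 || sigma <= 0) domain_error("k_prev and sigma must be positive")
  lp_prev <- log_unnormalized_posterior_k(k_prev, cprime, x, prior)
  prop <- k_prev + stats::rnorm(1L, 0, sigma)
  if (prop <= 0) {
    stats::runif(1L)  # consume the decision uniform so stubbing sigma does not shift the stream
    return(list(k = k_prev, accepted = FALSE, proposal = prop))
  }
  lp_prop <- log_unnormalized_posterior_k(prop, cprime, x, prior)
  acc <- log(stats::runif(1L)) <= lp_prop - lp_prev
  list(k = if (acc) prop else k_prev, accepted = acc, proposal = prop)
}

#' Gibbs sampler for one group's Weibull posterior
#'
#' Alternates the conjugate `c'` draw and the random-walk Metropolis shape
#' update for `iters` iterations, starting from the MLEs
#' (\eqn{k^{(0)} = \hat k}, \eqn{c'^{(0)} = (1/\hat c)^{\hat k}}).  During
#' burn-in the proposal scale is adapted every 50 iterations (multiplied or
#' divided by 1.1 to steer acceptance into [0.2, 0.5]) and then frozen, so
#' retained draws come from a fixed, detailed-balance-preserving kernel.
#'
#' @param x positive sample.
#' @param prior a [gamma_prior()].
#' @param iters total iterations (default 20000).
#' @param burn_in iterations discarded (default 1000), `0 < burn_in < iters`.
#' @param sigma_k0 initial proposal SD; default `0.1 * k_hat`.
#' @param adapt adapt the proposal scale during burn-in?
#' @param seed optional integer seed.
#' @param group optional label attached to the chain.
#' @return an object of class `"weibull_chain"`: retained vectors `k`,
#'   `cprime`, `c` (back-transformed scale), `mu` (per-iteration mean), the
#'   post-burn-in `accept_rate`, final `sigma_k`, `n`, `group`, `iters`,
#'   `burn_in`.
#' @export
gibbs_weibull <- function(x, prior = gamma_prior(), iters = 20000L,
                          burn_in = 1000L, sigma_k0 = NULL, adapt = TRUE,
                          seed = NULL, group = NULL) {
  if (burn_in <= 0L || burn_in >= iters)
    domain_error("need 0 < burn_in < iters")
  fit <- fit_weibull_mle(x, group = group)
  n <- fit$n
  lx <- log(x)
  slx <- sum(lx)
  v1 <- prior$v1; z1 <- prior$z1; v2 <- prior$v2; z2 <- prior$z2
  with_local_seed(seed, function() {
    k <- fit$k_hat
    sig <- if (is.null(sigma_k0)) 0.1 * fit$k_hat else sigma_k0
    if (sig <= 0) domain_error("sigma_k0 must be positive")
    K <- numeric(iters); CP <- numeric(iters)
    acc_post <- 0L; acc_win <- 0L
    sxk <- sum(exp(k * lx))
    lpk <- function(k, cp, sxk) (n + v1 - 1) * log(k) + (k - 1) * slx - z1 * k - cp * sxk
    for (t in seq_len(iters)) {
      cp <- stats::rgamma(1L, shape = n + v2, rate = z2 + sxk)
      lp <- lpk(k, cp, sxk)
      prop <- k + stats::rnorm(1L, 0, sig)
      u <- stats::runif(1L)
      if (prop > 0) {
        sxk_prop <- sum(exp(prop * lx))
        if (log(u) <= lpk(prop, cp, sxk_prop) - lp) {
          k <- prop; sxk <- sxk_prop
          acc_win <- acc_win + 1L
          if (t > burn_in) acc_post <- acc_post + 1L
        }
      }
      if (adapt && t <= burn_in && t %% 50L == 0L) {
        rate <- acc_win / 50
        acc_win <- 0L
        if (rate < 0.2) sig <- sig / 1.1 else if (rate > 0.5) sig <- sig * 1.1
      }
      K[t] <- k; CP[t] <- cp
    }
    keep <- (burn_in + 1L):iters
    kk <- K[keep]; cp <- CP[keep]
    cc <- (1 / cp)^(1 / kk)
    structure(list(k = kk, cprime = cp, c = cc,
                   mu = cc * gamma(1 + 1 / kk),
                   accept_rate = acc_post / length(keep),
                   sigma_k = sig, n = n, group = group,
                   iters = iters, burn_in = burn_in),
              class = "weibull_chain")
  })
}

#' Pool group posterior chains into common-mean draws
#'
#' Per retained iteration `t`, pools the group means
#' \eqn{\mu_i^{(t)} = c_i^{(t)}\Gamma(1+1/k_i^{(t)})} with weights
#' \eqn{1/\widehat{var}(\mu_i^{(t)})}, the delta-method variance with the
#' expected information evaluated at that iteration's parameters and the
#' group's sample size.
#'
#' @param chains list of [gibbs_weibull()] chains with equal retained length.
#' @return numeric vector of pooled common-mean draws.
#' @export
posterior_common_mean <- function(chains) {
  if (!is.list(chains) || length(chains) == 0L)
    domain_error("chains must be a non-empty list")
  len <- vapply(chains, function(h) length(h$mu), integer(1L))
  if (length(unique(len)) != 1L)
    domain_error("all chains must have the same retained length")
  if (length(chains) == 1L) return(chains[[1L]]$mu)
  mu <- vapply(chains, `[[`, numeric(len[1L]), "mu")
  v <- vapply(chains, function(h) delta_variance_expected(h$c, h$k, h$n),
              numeric(len[1L]))
  w <- 1 / v
  rowSums(mu * w) / rowSums(w)
}

#' Equitailed interval from Monte Carlo draws
#'
#' Empirical \eqn{\alpha/2} and \eqn{1-\alpha/2} quantiles (`type = 7`).
#'
#' @param draws numeric draws (at least 2).
#' @param level credibility level in (0, 1).
#' @param method label for the resulting interval.
#' @return a [new_interval()] object.
#' @export
equitailed_interval <- function(draws, level = 0.95, method = "bayes_equitailed") {
  if (length(draws) < 2L) domain_error("need at least 2 draws")
  if (level <= 0 || level >= 1) domain_error("level must be in (0, 1)")
  alpha <- 1 - level
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  new_interval(q[1L], q[2L], level, method)
}

#' Highest posterior density interval from Monte Carlo draws
#'
#' The shortest contiguous window of the sorted draws containing
#' `ceiling(level * N)` of the `N` draws.  By construction it is never
#' longer than the equitailed interval on the same draws.
#'
#' @inheritParams equitailed_interval
#' @return a [new_interval()] object with method `"bayes_hpd"`.
#' @export
hpd_interval <- function(draws, level = 0.95, method = "bayes_hpd") {
  if (length(draws) < 2L) domain_error("need at least 2 draws")
  if (level <= 0 || level >= 1) domain_error("level must be in (0, 1)")
  s <- sort(draws)
  N <- length(s)
  w <- ceiling(level * N)
  if (w >= N) return(new_interval(s[1L], s[N], level, method))
  width <- s[w:N] - s[1:(N - w + 1L)]
  j <- which.min(width)
  new_interval(s[j], s[j + w - 1L], level, method)
}

#' Bayesian credible intervals for the common Weibull mean
#'
#' Runs one Gibbs/RWM chain per group, pools the retained draws
#' iteration-wise, and returns both the equitailed and the HPD interval.
#'
#' @param samples a named list of positive numeric vectors, a single numeric
#'   vector, or a `group`/`value` data frame.
#' @param level credibility level.
#' @param prior a [gamma_prior()].
#' @param iters,burn_in chain length and burn-in per group.
#' @param seed optional integer seed; per-group chains use `seed`, `seed+1`,
#'   ... so the whole pipeline is reproducible.
#' @return a list with elements `equitailed` and `hpd` (both
#'   [new_interval()]), `draws` (pooled common-mean draws), `accept_rates`
#'   and `chains`.
#' @examples
#' wind <- surat_thani_wind()
#' fit <- bayes_common_mean(wind, iters = 2000, burn_in = 200, seed = 1)
#' fit$equitailed
#' fit$hpd
#' @export
bayes_common_mean <- function(samples, level = 0.95, prior = gamma_prior(),
                              iters = 20000L, burn_in = 1000L, seed = NULL) {
  samples <- as_sample_list(samples)
  seeds <- if (is.null(seed)) vector("list", length(samples)) else
    as.list(seed + seq_along(samples) - 1L)
  chains <- mapply(function(x, g, s) {
    gibbs_weibull(x, prior = prior, iters = iters, burn_in = burn_in,
                  seed = s, group = g)
  }, samples, names(samples), seeds, SIMPLIFY = FALSE)
  draws <- posterior_common_mean(chains)
  list(
    equitailed = equitailed_interval(draws, level),
    hpd = hpd_interval(draws, level),
    draws = draws,
    accept_rates = vapply(chains, `[[`, numeric(1L), "accept_rate"),
    chains = chains
  )
}
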