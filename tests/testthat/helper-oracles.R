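# Shared oracles and fixtures, independent of the implementation paths they
# check.

# Weibull log-likelihood in (k, c), written directly from the density.
weibull_loglik_kc <- function(par, x) {
  k <- par[1L]; cc <- par[2L]
  n <- length(x)
  n * log(k) - n * k * log(cc) + (k - 1) * sum(log(x)) - sum((x / cc)^k)
}

# Central finite-difference Hessian of f at par (independent of any analytic
# derivative in the package).
fd_hessian <- function(f, par, h = 1e-5 * pmax(abs(par), 1)) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- (f(par + ei + ej) - f(par + ei - ej) -
                f(par - ei + ej) + f(par - ei - ej)) / (4 * h[i] * h[j])
  }
  (H + t(H)) / 2
}

# Exhaustive shortest-window HPD used to cross-check the package's version.
brute_hpd <- function(draws, level = 0.95) {
  s <- sort(draws)
  N <- length(s)
  w <- ceiling(level * N)
  best <- c(-Inf, Inf)
  for (j in 1:(N - w + 1L)) {
    if (s[j + w - 1L] - s[j] < best[2L] - best[1L]) best <- c(s[j], s[j + w - 1L])
  }
  best
}

# Deterministic Weibull-like sample (quantile grid), handy where randomness
# would add nothing.
det_sample <- function(n, shape = 2, scale = 1) {
  qweibull(ppoints(n), shape = shape, scale = scale)
}

wind_fixture <- function() surat_thani_wind()
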