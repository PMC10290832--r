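test_that("the shape conditional vanishes off-support and reduces to its prior", {
  pr <- gamma_prior(2, 3, 1, 1)
  x <- c(0.5, 1.2, 2)
  expect_identical(log_unnormalized_posterior_k(c(-1, 0), 1, x, pr), c(-Inf, -Inf))
  # empty sample: the conditional is the gamma(v1, z1) prior up to a constant
  ks <- seq(0.2, 6, length.out = 25)
  diff <- log_unnormalized_posterior_k(ks, 1, numeric(0), pr) -
    dgamma(ks, shape = pr$v1, rate = pr$z1, log = TRUE)
  expect_lt(max(diff) - min(diff), 1e-10)
})

test_that("the shape conditional is a proper density under quadrature", {
  pr <- gamma_prior(1, 1, 1, 1)
  x <- c(0.8, 1.1, 1.9)
  lp <- function(k) exp(log_unnormalized_posterior_k(k, 0.7, x, pr))
  Z <- integrate(lp, 0, 60, rel.tol = 1e-10)$value
  expect_true(is.finite(Z) && Z > 0)
  dens <- function(k) lp(k) / Z
  expect_equal(integrate(dens, 0, 60, rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
})

test_that("the c' conditional is conjugate gamma with the stated shape and rate", {
  set.seed(51)
  pr <- gamma_prior(1e-4, 1e-4, 0.5, 0.7)
  x <- rweibull(20, 2, 1)
  k <- 1.7
  draws <- replicate(20000, sample_cprime(k, x, pr))
  shape <- length(x) + pr$v2
  rate <- pr$z2 + sum(x^k)
  ks <- suppressWarnings(ks.test(draws, pgamma, shape = shape, rate = rate))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(draws), shape / rate,
               tolerance = 4 * sqrt(shape) / rate / sqrt(20000) / (shape / rate))
})

test_that("random-walk Metropolis accepts null moves and rejects the negative axis", {
  set.seed(52)
  pr <- gamma_prior()
  x <- rweibull(15, 2, 1)
  # vanishing proposal scale: the ratio is ~1, every move accepted
  acc <- replicate(100, rwm_update_k(2, 1, x, pr, sigma = 1e-12)$accepted)
  expect_true(all(acc))
  # huge proposal scale from a small state: non-positive proposals always rejected
  res <- replicate(300, {
    u <- rwm_update_k(0.05, 1, x, pr, sigma = 10)
    c(u$proposal, u$accepted, u$k)
  })
  neg <- res[1, ] <= 0
  expect_true(any(neg))
  expect_true(all(res[2, neg] == 0))
  expect_true(all(res[3, neg] == 0.05))
})

test_that("RWM long-run distribution matches the quadrature-normalized conditional", {
  set.seed(53)
  pr <- gamma_prior(1, 1, 1, 1)
  x <- c(0.8, 1.1, 1.9)
  cp <- 0.7
  lp <- function(k) exp(log_unnormalized_posterior_k(k, cp, x, pr))
  Z <- integrate(lp, 0, 80, rel.tol = 1e-10)$value
  cdf <- Vectorize(function(q) integrate(lp, 0, q, rel.tol = 1e-9)$value / Z)
  k <- 1
  draws <- numeric(60000)
  for (t in seq_along(draws)) {
    k <- rwm_update_k(k, cp, x, pr, sigma = 1.2)$k
    draws[t] <- k
  }
  draws <- draws[-(1:2000)]
  grid <- quantile(draws, seq(0.02, 0.98, by = 0.02), names = FALSE)
  emp <- ecdf(draws)(grid)
  expect_lt(max(abs(emp - cdf(grid))), 0.02)
})

test_that("the Gibbs chain is seed-deterministic and concentrates near the MLE", {
  wind <- wind_fixture()
  x <- wind[["Khiri Rat Nikhom"]]
  a <- gibbs_weibull(x, iters = 800, burn_in = 200, seed = 61)
  b <- gibbs_weibull(x, iters = 800, burn_in = 200, seed = 61)
  expect_identical(a$mu, b$mu)
  expect_identical(a$k, b$k)
  long <- gibbs_weibull(x, iters = 8000, burn_in = 1000, seed = 62)
  expect_equal(mean(long$mu), 0.83, tolerance = 0.025)
  expect_equal(long$c, (1 / long$cprime)^(1 / long$k))
})

test_that("adapted acceptance rates land in a healthy band on all wind groups", {
  wind <- wind_fixture()
  for (g in names(wind)) {
    ch <- gibbs_weibull(wind[[g]], iters = 5000, burn_in = 1000, seed = 63)
    expect_gt(ch$accept_rate, 0.15)
    expect_lt(ch$accept_rate, 0.6)
  }
})

test_that("posterior pooling is convex and respects equal weights", {
  # one chain: pooled draws are its own mean draws
  ch <- gibbs_weibull(det_sample(30), iters = 600, burn_in = 100, seed = 64)
  expect_identical(posterior_common_mean(list(ch)), ch$mu)
  # equal (c, k, n) across groups forces equal weights: pooled = average
  mk <- function(mu_shift) {
    structure(list(k = rep(2, 50), c = rep(1, 50),
                   mu = rep(1, 50) + mu_shift, n = 30L), class = "weibull_chain")
  }
  pooled <- posterior_common_mean(list(mk(0), mk(0.4)))
  expect_equal(pooled, rep(1.2, 50))
  # convexity per iteration on real chains
  wind <- wind_fixture()
  chains <- lapply(seq_along(wind), function(i)
    gibbs_weibull(wind[[i]], iters = 700, burn_in = 100, seed = 70 + i))
  mus <- sapply(chains, `[[`, "mu")
  pooled <- posterior_common_mean(chains)
  expect_true(all(pooled >= apply(mus, 1, min) - 1e-12))
  expect_true(all(pooled <= apply(mus, 1, max) + 1e-12))
  expect_error(posterior_common_mean(list(chains[[1]], mk(0))),
               class = "weibullcm_domain_error")
})

test_that("equitailed and HPD intervals have the stated small-sample behavior", {
  expect_error(equitailed_interval(1), class = "weibullcm_domain_error")
  v <- rep(3.2, 100)
  ci <- equitailed_interval(v)
  expect_equal(c(ci$lower, ci$upper), c(3.2, 3.2))
  hp <- hpd_interval(v)
  expect_equal(c(hp$lower, hp$upper), c(3.2, 3.2))
  set.seed(65)
  z <- rnorm(200000)
  ci <- equitailed_interval(z, 0.95)
  expect_equal(c(ci$lower, ci$upper), c(-1.96, 1.96), tolerance = 0.02)
  # symmetric unimodal draws: HPD ~ equitailed
  hp <- hpd_interval(z, 0.95)
  expect_equal(c(hp$lower, hp$upper), c(ci$lower, ci$upper), tolerance = 0.03)
})

test_that("HPD is the shortest window, never longer than equitailed, and shifts under skew", {
  set.seed(66)
  for (i in 1:25) {
    draws <- switch(1 + i %% 3,
                    rexp(400), rnorm(300), rgamma(500, shape = 2))
    lv <- sample(c(0.8, 0.9, 0.95), 1)
    hp <- hpd_interval(draws, lv)
    et <- equitailed_interval(draws, lv)
    expect_lte(hp$length, et$length + 1e-12)
    expect_equal(c(hp$lower, hp$upper), brute_hpd(draws, lv))
  }
  set.seed(67)
  skewed <- rexp(20000)
  expect_lt(hpd_interval(skewed)$lower, equitailed_interval(skewed)$lower)
})

test_that("the 95% HPD for the mean covers the truth across replicate chains", {
  set.seed(68)
  k_true <- 2.5; c_true <- 1.5
  mu_true <- weibull_mean(c_true, k_true)
  hits <- 0L
  for (r in 1:100) {
    x <- rweibull(500, shape = k_true, scale = c_true)
    ch <- gibbs_weibull(x, iters = 2000, burn_in = 200)
    hp <- hpd_interval(ch$mu, 0.95)
    hits <- hits + (hp$lower <= mu_true && mu_true <= hp$upper)
  }
  expect_gte(hits, 90L)
})

test_that("the full pipeline is reproducible and internally consistent", {
  wind <- wind_fixture()
  a <- bayes_common_mean(wind, iters = 1500, burn_in = 300, seed = 71)
  b <- bayes_common_mean(wind, iters = 1500, burn_in = 300, seed = 71)
  expect_identical(a$draws, b$draws)
  expect_identical(c(a$equitailed$lower, a$equitailed$upper),
                   c(b$equitailed$lower, b$equitailed$upper))
  expect_lte(a$hpd$length, a$equitailed$length)
  expect_length(a$accept_rates, 3L)
})
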