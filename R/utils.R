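# Internal helpers: error conditions, seed scoping, the vectorized profile-score
# solver, and closed-form expected-information quantities.

input_error <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("weibullcm_input_error", "error"), call = call))
}

domain_error <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("weibullcm_domain_error", "error"), call = call))
}

estimation_error <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("weibullcm_estimation_error", "error"), call = call))
}

# Evaluate fn() under a locally-set RNG seed, restoring the caller's RNG state
# afterwards so seeded calls do not perturb an enclosing stream.
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

# Profile-score for the Weibull shape: g(k) = 1/k - sum(x^k log x)/sum(x^k)
# + mean(log x).  Solved row-wise on a matrix of log-observations with a
# bracketed, safeguarded Newton iteration (bisection fallback keeps every
# iterate inside a sign-changing bracket, so convergence is guaranteed for
# non-degenerate rows).  Row computations shift log x by its row maximum so
# x^k never overflows.
solve_shape_rows <- function(lX, tol = 1e-12, max_iter = 120L) {
  if (!is.matrix(lX)) lX <- matrix(lX, nrow = 1L)
  n <- ncol(lX)
  mlx <- rowMeans(lX)
  mx <- apply(lX, 1L, max)
  lS <- lX - mx                      # shifted logs, <= 0
  rsd <- sqrt(pmax(rowSums((lX - mlx)^2) / (n - 1), 0))
  k0 <- 1.2 / rsd
  k0[!is.finite(k0) | k0 <= 0] <- 1

  score <- function(k) {
    t <- exp(k * lS)
    st <- rowSums(t)
    1 / k - rowSums(t * lX) / st + mlx
  }

  lo <- k0 / 100
  hi <- k0 * 100
  # expand brackets where the sign change is not yet captured (rare)
  for (rep in 1:4) {
    bad_lo <- score(lo) <= 0
    if (!any(bad_lo)) break
    lo[bad_lo] <- lo[bad_lo] / 100
  }
  for (rep in 1:4) {
    bad_hi <- score(hi) >= 0
    if (!any(bad_hi)) break
    hi[bad_hi] <- hi[bad_hi] * 100
  }
  ok <- score(lo) > 0 & score(hi) < 0

  k <- k0
  for (it in seq_len(max_iter)) {
    t <- exp(k * lS)
    st <- rowSums(t)
    s1 <- rowSums(t * lX)
    s2 <- rowSums(t * lX^2)
    gk <- 1 / k - s1 / st + mlx
    pos <- gk > 0
    lo[pos] <- k[pos]
    hi[!pos] <- k[!pos]
    gp <- -1 / k^2 - (s2 * st - s1^2) / st^2
    kn <- k - gk / gp
    use_mid <- !is.finite(kn) | kn <= lo | kn >= hi
    kn[use_mid] <- (lo[use_mid] + hi[use_mid]) / 2
    done <- max(abs(kn - k), na.rm = TRUE) < tol
    k <- kn
    if (done) break
  }
  k[!ok] <- NA_real_
  k
}

# Profile scale given shape: c = (mean(x^k))^(1/k), computed on the log scale.
profile_scale <- function(x, k) {
  lx <- log(x)
  mx <- max(lx)
  exp(mx + log(mean(exp(k * (lx - mx)))) / k)
}

profile_scale_rows <- function(lX, k) {
  mx <- apply(lX, 1L, max)
  exp(mx + log(rowMeans(exp(k * (lX - mx)))) / k)
}

EULER_GAMMA <- 0.57721566490153286

# Closed-form inverse expected (Fisher) information entries for the Weibull
# MLEs at (c, k), sample size n; vectorized over c and k.
expected_info_inverse_entries <- function(c, k, n) {
  om <- 1 - EULER_GAMMA
  list(
    var_k = 6 * k^2 / (n * pi^2),
    var_c = c^2 / (n * k^2) * (1 + 6 * om^2 / pi^2),
    cov_kc = 6 * c * om / (n * pi^2)
  )
}

# Delta-method variance of mu = c * gamma(1 + 1/k) from inverse-information
# entries; vectorized.
delta_variance_entries <- function(c, k, var_k, var_c, cov_kc) {
  G <- gamma(1 + 1 / k)
  dmu_dk <- -(c / k^2) * G * digamma(1 + 1 / k)
  dmu_dc <- G
  var_k * dmu_dk^2 + 2 * cov_kc * dmu_dk * dmu_dc + var_c * dmu_dc^2
}

# Expected-information delta variance of the Weibull mean; vectorized.
delta_variance_expected <- function(c, k, n) {
  e <- expected_info_inverse_entries(c, k, n)
  delta_variance_entries(c, k, e$var_k, e$var_c, e$cov_kc)
}

# Coerce the various accepted sample containers to a named list of numeric
# vectors; validates positivity and minimum size.
as_sample_list <- function(samples) {
  if (is.numeric(samples)) samples <- list(samples)
  if (is.data.frame(samples)) {
    if (!all(c("group", "value") %in% names(samples)))
      input_error("data frame input must have columns 'group' and 'value'")
    samples <- split(samples$value, factor(samples$group, levels = unique(samples$group)))
  }
  if (!is.list(samples) || length(samples) == 0L)
    input_error("samples must be a numeric vector, a list of numeric vectors, or a group/value data frame")
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("group", seq_along(samples))
  for (g in names(samples)) {
    x <- samples[[g]]
    if (!is.numeric(x) || length(x) < 2L)
      domain_error(sprintf("group '%s': at least 2 numeric observations are required", g))
    if (any(!is.finite(x)) || any(x <= 0))
      domain_error(sprintf("group '%s': all observations must be finite and strictly positive", g))
  }
  samples
}
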