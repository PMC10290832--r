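#' Construct an interval object
#'
#' Light container used by every interval method in the package.
#'
#' @param lower,upper interval endpoints, `lower <= upper`.
#' @param level confidence/credibility level in (0, 1).
#' @param method label identifying the construction.
#' @return a list of class `"weibull_interval"` with elements `lower`,
#'   `upper`, `level`, `method` and `length`.
#' @export
new_interval <- function(lower, upper, level, method) {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    domain_error("interval endpoints must be finite with lower <= upper")
  if (level <= 0 || level >= 1) domain_error("level must be in (0, 1)")
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, length = upper - lower),
            class = "weibull_interval")
}

#' @export
print.weibull_interval <- function(x, digits = 4L, ...) {
  cat(sprintf("%.0f%% interval (%s): [%.*f, %.*f], length %.*f\n",
              100 * x$level, x$method, digits, x$lower, digits, x$upper,
              digits, x$length))
  invisible(x)
}
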