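# Interval containers and the quantile-based interval constructors shared by
# the fiducial and Bayesian methods.

#' Method-tagged confidence/credible interval
#'
#' @param method one of \code{"FGCI"}, \code{"EB_Jeffreys"},
#'   \code{"EB_Uniform"}, \code{"HPD_Jeffreys"}, \code{"HPD_Uniform"},
#'   \code{"MOVER"}.
#' @param level nominal confidence level in (0, 1).
#' @param lower,upper interval endpoints, \code{0 < lower <= upper}.
#' @return Object of class \code{cv_interval} with a \code{length} field.
#' @export
cv_interval <- function(method, level, lower, upper) {
  method <- match.arg(method, c("FGCI", "EB_Jeffreys", "EB_Uniform",
                                "HPD_Jeffreys", "HPD_Uniform", "MOVER"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  if (is.na(lower) || is.na(upper) || lower < 0 || lower > upper)
    stop("need 0 <= lower <= upper", call. = FALSE)
  structure(list(method = method, level = level,
                 lower = lower, upper = upper, length = upper - lower),
            class = "cv_interval")
}

#' @export
print.cv_interval <- function(x, ...) {
  cat(sprintf("%s %.0f%% interval: (%.4f, %.4f), length %.4f\n",
              x$method, 100 * x$level, x$lower, x$upper, x$length))
  invisible(x)
}

check_draws <- function(draws, min_draws = 100L) {
  if (is.list(draws) && !is.null(draws$eta)) draws <- draws$eta
  draws <- as.numeric(draws)
  if (length(draws) < min_draws)
    stop("need at least ", min_draws, " Monte Carlo draws", call. = FALSE)
  # +Inf draws are legitimate: the substituted variance form can turn
  # negative for draws of delta well below the observed rate, so the weight
  # sum can pass near zero and blow the common-CV draw up.  Such draws sit
  # in the far right tail and are kept, not filtered.
  if (any(is.na(draws)))
    stop("NA/NaN draws", call. = FALSE)
  draws
}

# Equal-tailed percentile interval with linear-interpolation quantiles
# (stats::quantile type 7), the convention used throughout the package.
percentile_interval <- function(draws, level, method) {
  draws <- check_draws(draws)
  alpha <- 1 - level
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2),
                       names = FALSE, type = 7)
  cv_interval(method, level, q[1L], q[2L])
}

#' Equal-tailed interval from Monte Carlo draws
#'
#' Cuts \code{(1 - level)/2} of the draws from each tail, using
#' linear-interpolation empirical quantiles.
#'
#' @param draws numeric vector of common-CV draws (pivotal or posterior), or
#'   a draw object with an \code{eta} component; at least 100 draws.
#' @param level nominal confidence level.
#' @param method method tag for the resulting interval.
#' @return A [cv_interval()].
#' @export
equal_tailed_interval <- function(draws, level = 0.95, method = "EB_Jeffreys") {
  percentile_interval(draws, level, method)
}

#' Highest posterior density interval from Monte Carlo draws
#'
#' The shortest contiguous window of the sorted draws containing
#' \code{ceiling(level * K)} of the \code{K} draws; ties are broken by the
#' leftmost window.
#'
#' @inheritParams equal_tailed_interval
#' @return A [cv_interval()].
#' @export
hpd_interval <- function(draws, level = 0.95, method = "HPD_Jeffreys") {
  draws <- check_draws(draws)
  s <- sort(draws)
  k <- length(s)
  m <- ceiling(level * k)
  widths <- s[m:k] - s[1:(k - m + 1L)]
  i <- which.min(widths)            # which.min takes the leftmost tie
  cv_interval(method, level, s[i], s[i + m - 1L])
}
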