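#' @keywords internal
"_PACKAGE"

# Parameter checks shared by the distribution primitives.  delta is the
# probability of a non-zero observation; (mu, sigma2) are the mean and
# variance of the log of the non-zero part.
check_dln_params <- function(delta, mu, sigma2) {
  if (any(!is.finite(delta)) || any(delta <= 0) || any(delta > 1))
    stop("'delta' must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(mu)))
    stop("'mu' must be finite", call. = FALSE)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("'sigma2' must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Delta-lognormal density
#'
#' Density of the delta-lognormal (zero-inflated lognormal) distribution: a
#' point mass of size \code{1 - delta} at zero, and \code{delta} times the
#' lognormal density for positive values.  At \code{x = 0} the returned value
#' is the point mass \code{1 - delta}, not a density.
#'
#' @param x vector of non-negative quantiles.
#' @param delta probability of a non-zero observation, in (0, 1].
#' @param mu mean of the log of the non-zero part.
#' @param sigma2 variance of the log of the non-zero part, positive.
#' @return Numeric vector: \code{1 - delta} where \code{x == 0}, otherwise
#'   \code{delta * dlnorm(x, mu, sqrt(sigma2))}.
#' @examples
#' ddln(0, delta = 0.7)                 # point mass 0.3
#' ddln(1, delta = 1, mu = 0, sigma2 = 1)  # standard lognormal at its median
#' @export
ddln <- function(x, delta, mu = 0, sigma2 = 1) {
  check_dln_params(delta, mu, sigma2)
  if (any(x < 0)) stop("'x' must be non-negative", call. = FALSE)
  ifelse(x == 0, 1 - delta,
         delta * stats::dlnorm(x, meanlog = mu, sdlog = sqrt(sigma2)))
}

#' Sample from a delta-lognormal distribution
#'
#' Each observation is zero with probability \code{1 - delta} and otherwise
#' \code{exp(Normal(mu, sigma2))}.  Uses R's global random number generator;
#' set a seed for reproducibility.
#'
#' @param n number of observations.
#' @inheritParams ddln
#' @return Numeric vector of length \code{n} of non-negative values.
#' @export
rdln <- function(n, delta, mu = 0, sigma2 = 1) {
  check_dln_params(delta, mu, sigma2)
  nonzero <- stats::runif(n) < delta
  x <- numeric(n)
  k <- sum(nonzero)
  if (k > 0)
    x[nonzero] <- stats::rlnorm(k, meanlog = mu, sdlog = sqrt(sigma2))
  x
}

#' Mean and variance of a delta-lognormal distribution
#'
#' @inheritParams ddln
#' @return List with components \code{mean = delta * exp(mu + sigma2/2)} and
#'   \code{variance = delta * exp(2*mu + sigma2) * (exp(sigma2) - delta)}.
#' @export
dln_moments <- function(delta, mu = 0, sigma2 = 1) {
  check_dln_params(delta, mu, sigma2)
  list(mean = delta * exp(mu + sigma2 / 2),
       variance = delta * exp(2 * mu + sigma2) * (exp(sigma2) - delta))
}

#' Log coefficient of variation of a delta-lognormal distribution
#'
#' Computes \eqn{\varphi = \frac12\{\log[\exp(\sigma^2) - \delta] -
#' \log\delta\}}, the log of the CV.  Evaluated in log space as
#' \code{(sigma2 + log1p(-delta * exp(-sigma2)) - log(delta)) / 2} so that
#' very large \code{sigma2} (posterior or pivotal draws can exceed 700, where
#' \code{exp} overflows) still yields a finite value.
#'
#' @param sigma2 log-scale variance(s), positive; vector or matrix.
#' @param delta non-zero probability(ies) in (0, 1]; recycled against
#'   \code{sigma2}.
#' @return \code{phi}, same shape as the recycled arguments.
#' @seealso [dln_cv()] for the CV itself, \code{exp(phi)}.
#' @export
phi_log_cv <- function(sigma2, delta) {
  if (any(delta <= 0) || any(delta > 1))
    stop("'delta' must lie in (0, 1]", call. = FALSE)
  if (any(sigma2 <= 0))
    stop("'sigma2' must be positive", call. = FALSE)
  0.5 * (sigma2 + log1p(-delta * exp(-sigma2)) - log(delta))
}

#' Coefficient of variation of a delta-lognormal distribution
#'
#' The CV is \eqn{\eta = \sqrt{(\exp(\sigma^2) - \delta)/\delta}}; it does not
#' depend on \code{mu}.
#'
#' @inheritParams phi_log_cv
#' @return Positive CV value(s), \code{exp(phi_log_cv(sigma2, delta))}.
#' @export
dln_cv <- function(delta, sigma2) {
  exp(phi_log_cv(sigma2, delta))
}
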