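# Fiducial generalized confidence interval (FGCI) for the common CV.
#
# Per group, fiducial pivotal quantities are drawn for delta (an equal-weight
# mixture of two beta laws) and sigma2 (scaled inverse chi-square anchored at
# the sample variance); the per-draw common CV is then formed exactly as the
# point estimate, with the draws substituted for the data estimates.

# Shared by the fiducial and Bayesian routes: given draws x groups matrices
# of delta and sigma2 values and the fixed group sizes, compute the per-draw
# phi, variance (functional form of the observed-data variance), weight and
# common CV.
common_cv_draw_matrix <- function(delta, sigma2, n, n1,
                                  floor_binomial = FALSE) {
  K <- nrow(delta)
  k <- ncol(delta)
  nm  <- matrix(n,  K, k, byrow = TRUE)
  n1m <- matrix(n1, K, k, byrow = TRUE)
  phi <- phi_log_cv(sigma2, delta)
  v <- var_phi_form(delta, sigma2, nm, n1m, floor_binomial)
  w <- 1 / v
  eta <- exp(rowSums(w * phi) / rowSums(w))
  list(phi = phi, var = v, weight = w, eta = eta)
}

#' Fiducial pivotal draws for the non-zero probability
#'
#' Draws from the half-half mixture of \code{Beta(n1, n0 + 1)} and
#' \code{Beta(n1 + 1, n0)}.  A beta component with a zero second shape is the
#' degenerate point mass at 1 (it arises when no zeros were observed), so all
#' draws lie in (0, 1].
#'
#' @param n1 observed non-zero count, at least 1.
#' @param n0 observed zero count.
#' @param draws number of pivotal draws.
#' @return Numeric vector of length \code{draws} with values in (0, 1].
#' @export
pivotal_delta <- function(n1, n0, draws) {
  if (n1 < 1L) stop("'n1' must be at least 1", call. = FALSE)
  if (n0 < 0L) stop("'n0' must be non-negative", call. = FALSE)
  use_first <- stats::runif(draws) < 0.5
  out <- numeric(draws)
  k1 <- sum(use_first)
  if (k1 > 0) out[use_first] <- stats::rbeta(k1, n1, n0 + 1)
  k2 <- draws - k1
  if (k2 > 0) {
    out[!use_first] <- if (n0 == 0L) 1 else stats::rbeta(k2, n1 + 1, n0)
  }
  out
}

#' Fiducial pivotal draws for the log-scale variance
#'
#' Draws \code{(n1 - 1) * sigma2_hat / U} with \code{U ~ chi-square(n1 - 1)}.
#'
#' @param n1 observed non-zero count, at least 2.
#' @param sigma2_hat unbiased sample variance of the log non-zero values.
#' @param draws number of pivotal draws.
#' @return Numeric vector of positive draws.
#' @export
pivotal_sigma2 <- function(n1, sigma2_hat, draws) {
  if (n1 < 2L) stop("'n1' must be at least 2", call. = FALSE)
  (n1 - 1) * sigma2_hat / stats::rchisq(draws, df = n1 - 1)
}

#' Fiducial pivotal draws of the common CV
#'
#' For every draw and group, substitutes the pivotal delta and sigma2 values
#' into the log-CV, into the variance form behind the weights, and into the
#' weighted combination, yielding one common-CV pivotal value per draw.
#'
#' The substituted variance form carries the same numerical guard as the
#' posterior sampler: its binomial contribution is floored at zero.  Without
#' the guard the contribution is negative for every draw of delta below
#' roughly \code{(n1-1)/(n-1)} — about half of all draws, at any sample
#' size — so weight sums cross zero, single draws escape to infinity, and
#' the interval stops narrowing as \code{n} grows.  See the methods
#' vignette.
#'
#' @param summaries list of non-degenerate [dln_summary()] objects.
#' @param draws number of Monte Carlo draws (default 2000).
#' @return Object of class \code{cv_draws}: list with matrices \code{delta},
#'   \code{sigma2}, \code{phi}, \code{weight} (draws x groups) and the vector
#'   \code{eta} of per-draw common-CV values.
#' @export
pivotal_common_cv <- function(summaries, draws = 2000L) {
  summaries <- check_nondegenerate(summaries)
  k <- length(summaries)
  delta <- vapply(summaries, function(s) pivotal_delta(s$n1, s$n0, draws),
                  numeric(draws))
  sigma2 <- vapply(summaries,
                   function(s) pivotal_sigma2(s$n1, s$sigma2_hat, draws),
                   numeric(draws))
  delta <- matrix(delta, draws, k)
  sigma2 <- matrix(sigma2, draws, k)
  parts <- common_cv_draw_matrix(delta, sigma2,
                                 vapply(summaries, `[[`, numeric(1), "n"),
                                 vapply(summaries, `[[`, numeric(1), "n1"),
                                 floor_binomial = TRUE)
  structure(c(list(method = "FGCI", delta = delta, sigma2 = sigma2), parts),
            class = "cv_draws")
}

#' Percentile interval from fiducial pivotal draws
#'
#' @param draws vector of common-CV pivotal draws, or a \code{cv_draws}
#'   object from [pivotal_common_cv()]; at least 100 draws.
#' @param level nominal confidence level.
#' @return A [cv_interval()] tagged \code{FGCI}.
#' @export
fgci_interval <- function(draws, level = 0.95) {
  percentile_interval(draws, level, "FGCI")
}

#' Fiducial generalized confidence interval for the common CV
#'
#' Convenience wrapper: draws the pivotal quantities and returns the
#' equal-tailed percentile interval of the common-CV pivot.
#'
#' @inheritParams pivotal_common_cv
#' @param level nominal confidence level.
#' @return A [cv_interval()] tagged \code{FGCI}.
#' @export
fgci_common_cv <- function(summaries, level = 0.95, draws = 2000L) {
  fgci_interval(pivotal_common_cv(summaries, draws), level)
}
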