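# Per-group sufficient statistics and the weighted common CV.

#' Construct a per-group summary of delta-lognormal data
#'
#' A \code{dln_summary} holds the sufficient statistics of one group:
#' total count \code{n}, non-zero count \code{n1}, zero count \code{n0},
#' \code{delta_hat = n1/n}, and the sample mean \code{mu_hat} and unbiased
#' sample variance \code{sigma2_hat} of the log of the non-zero values.
#'
#' Summaries transcribed from a report usually give \code{delta_hat} to a few
#' decimals instead of \code{n1}; in that case \code{n1} is recovered as
#' \code{round(delta_hat * n)} and the rounding must be consistent to within
#' 0.01.  A group with fewer than two non-zero observations has no variance
#' estimate and is flagged degenerate; every interval method rejects it.
#'
#' @param n total number of observations.
#' @param n1 number of non-zero observations; may be omitted when
#'   \code{delta_hat} is given.
#' @param sigma2_hat unbiased sample variance of the log non-zero values.
#' @param mu_hat sample mean of the log non-zero values (optional; not used
#'   by the CV methods).
#' @param delta_hat observed non-zero proportion, used to recover \code{n1}.
#' @param group optional group label.
#' @return Object of class \code{dln_summary}.
#' @examples
#' dln_summary(n = 62, delta_hat = 0.7258, sigma2_hat = 1.7857)
#' @export
dln_summary <- function(n, n1 = NULL, sigma2_hat = NA_real_,
                        mu_hat = NA_real_, delta_hat = NULL, group = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a positive count", call. = FALSE)
  if (is.null(n1)) {
    if (is.null(delta_hat))
      stop("supply either 'n1' or 'delta_hat'", call. = FALSE)
    n1 <- round(delta_hat * n)
    if (abs(delta_hat * n - n1) >= 0.01 * n)
      stop("'delta_hat' is inconsistent with an integer non-zero count",
           call. = FALSE)
  }
  n1 <- as.integer(n1)
  if (is.na(n1) || n1 < 0L || n1 > n)
    stop("'n1' must lie in 0..n", call. = FALSE)
  degenerate <- n1 < 2L
  if (!degenerate && (is.na(sigma2_hat) || sigma2_hat < 0))
    stop("'sigma2_hat' must be a non-negative number", call. = FALSE)
  structure(list(group = if (is.null(group)) NA_character_ else as.character(group),
                 n = n, n1 = n1, n0 = n - n1,
                 delta_hat = n1 / n,
                 mu_hat = as.numeric(mu_hat),
                 sigma2_hat = if (degenerate) NA_real_ else as.numeric(sigma2_hat),
                 degenerate = degenerate),
            class = "dln_summary")
}

#' @export
print.dln_summary <- function(x, ...) {
  cat(sprintf("delta-lognormal group summary%s\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]")))
  cat(sprintf("  n = %d, n1 = %d, n0 = %d, delta_hat = %.4f\n",
              x$n, x$n1, x$n0, x$delta_hat))
  if (x$degenerate) {
    cat("  degenerate: fewer than 2 non-zero observations\n")
  } else {
    cat(sprintf("  mu_hat = %.4f, sigma2_hat = %.4f\n", x$mu_hat, x$sigma2_hat))
  }
  invisible(x)
}

#' Summarize one vector of delta-lognormal observations
#'
#' @param x numeric vector of non-negative observations; exact zeros count as
#'   zero-class observations (no tolerance).
#' @param group optional group label.
#' @return A [dln_summary()].  If fewer than two entries are positive the
#'   summary is flagged degenerate and carries no \code{sigma2_hat}.
#' @export
summarize_dln <- function(x, group = NULL) {
  if (length(x) == 0L) stop("empty observation vector", call. = FALSE)
  if (any(is.na(x))) stop("missing values in observations", call. = FALSE)
  if (any(x < 0)) stop("negative observations are not allowed", call. = FALSE)
  lx <- log(x[x > 0])
  n1 <- length(lx)
  dln_summary(n = length(x), n1 = n1,
              mu_hat = if (n1 >= 1L) mean(lx) else NA_real_,
              sigma2_hat = if (n1 >= 2L) stats::var(lx) else NA_real_,
              group = group)
}

#' @rdname dln_summary
#' @param x object to test.
#' @export
is_degenerate <- function(x) {
  stopifnot(inherits(x, "dln_summary"))
  isTRUE(x$degenerate)
}

check_nondegenerate <- function(summaries) {
  if (inherits(summaries, "dln_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) stop("no group summaries supplied", call. = FALSE)
  ok <- vapply(summaries, inherits, logical(1), what = "dln_summary")
  if (!all(ok)) stop("all groups must be 'dln_summary' objects", call. = FALSE)
  bad <- vapply(summaries, is_degenerate, logical(1))
  if (any(bad))
    stop("degenerate group(s) with fewer than 2 non-zero observations: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  summaries
}

# Variance of phi-hat as a function of (delta, sigma2) with the group sizes
# (n, n1) held fixed.  Used with data estimates for the observed variance and
# with pivotal/posterior draws substituted for (delta, sigma2); all arguments
# vectorize elementwise.
#
# The first (binomial) term is non-negative at the data estimates
# (delta = n1/n) but turns negative when a substituted delta falls below
# roughly (n1 - 1)/(n - 1).  floor_binomial = TRUE floors that contribution
# at zero, which keeps the substituted form a valid (positive) variance; the
# posterior sampler uses the floored form for its weights.
var_phi_form <- function(delta, sigma2, n, n1, floor_binomial = FALSE) {
  a <- (1 - delta)^(n - 1)
  b <- 1 + (n - 1) * delta
  binom <- ((b - a) * (1 - a * b) - n1 * (1 - a)^2) / (4 * n1 * (1 - a)^2)
  if (floor_binomial) binom <- pmax(binom, 0)
  binom + sigma2^2 / (2 * (n1 - 1))
}

#' Estimated variance of the log-CV estimator
#'
#' Approximately unbiased variance estimate of \eqn{\hat\varphi}, combining a
#' term for the estimated zero probability (through
#' \eqn{\hat a = (1-\hat\delta)^{n-1}} and
#' \eqn{\hat b = 1 + (n-1)\hat\delta}) with the chi-square variance term
#' \eqn{\hat\sigma^4 / [2(n_1 - 1)]}.  Its reciprocal is the weight of the
#' group in the common log-CV.
#'
#' @param summary a non-degenerate [dln_summary()] (needs \code{n1 >= 2}).
#' @return Positive variance estimate.
#' @export
var_phi_hat <- function(summary) {
  summary <- check_nondegenerate(summary)[[1L]]
  var_phi_form(summary$delta_hat, summary$sigma2_hat, summary$n, summary$n1)
}

#' Precision-weighted common log-CV
#'
#' @param phis per-group log-CV estimates.
#' @param weights positive weights, conventionally the reciprocal
#'   [var_phi_hat()] variances.
#' @return The weighted mean \code{sum(weights * phis) / sum(weights)}.
#' @export
common_log_cv <- function(phis, weights) {
  if (length(phis) == 0L) stop("empty input", call. = FALSE)
  if (length(phis) != length(weights))
    stop("'phis' and 'weights' must have equal length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  sum(weights * phis) / sum(weights)
}

#' Common coefficient of variation of several delta-lognormal groups
#'
#' Point estimate of the common CV: the exponential of the precision-weighted
#' mean of the per-group log-CV estimates, with weights equal to the
#' reciprocal estimated variances from [var_phi_hat()].
#'
#' @param summaries list of non-degenerate [dln_summary()] objects.
#' @return Positive common-CV estimate.
#' @examples
#' rain <- list(
#'   dln_summary(62, delta_hat = 0.7258, sigma2_hat = 1.7857),
#'   dln_summary(62, delta_hat = 0.7903, sigma2_hat = 3.4406),
#'   dln_summary(62, delta_hat = 0.7419, sigma2_hat = 1.8346))
#' common_cv(rain)
#' @export
common_cv <- function(summaries) {
  summaries <- check_nondegenerate(summaries)
  phis <- vapply(summaries, function(s) phi_log_cv(s$sigma2_hat, s$delta_hat),
                 numeric(1))
  vars <- vapply(summaries, var_phi_hat, numeric(1))
  exp(common_log_cv(phis, 1 / vars))
}
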