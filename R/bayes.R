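# Bayesian intervals for the common CV under two conjugate-style priors.
#
# The model factorizes per group: the zero/non-zero split is binomial in
# delta* = 1 - delta, and the log non-zero values are normal.  Under the
# independent Jeffreys prior the posteriors are
#   delta* | x ~ Beta(n0 + 1/2, n1 + 1/2)
#   sigma2 | x ~ Inv-Gamma((n1 - 1)/2, (n1 - 1) sigma2_hat / 2)
# and under the uniform prior
#   delta* | x ~ Beta(n0 + 1, n1 + 1)
#   sigma2 | x ~ Inv-Gamma((n1 - 2)/2, (n1 - 2) sigma2_hat / 2).
# The common-CV posterior is induced by pushing joint draws through the same
# weighted log-CV combination used for the point estimate.

#' Posterior parameters for one group
#'
#' @param summary a non-degenerate [dln_summary()].
#' @param prior \code{"jeffreys"} (needs \code{n1 >= 2}) or \code{"uniform"}
#'   (needs \code{n1 >= 3} for a positive inverse-gamma shape).
#' @return List with the beta parameters \code{beta_a}, \code{beta_b} of the
#'   posterior of \code{delta* = 1 - delta}, and the inverse-gamma
#'   \code{ig_shape}, \code{ig_scale} of the posterior of \code{sigma2}.
#' @examples
#' s <- dln_summary(62, n1 = 45, sigma2_hat = 1.7857)
#' posterior_parameters(s, "jeffreys")  # Beta(17.5, 45.5), IG(22, 39.2854)
#' @export
posterior_parameters <- function(summary, prior = c("jeffreys", "uniform")) {
  prior <- match.arg(prior)
  summary <- check_nondegenerate(summary)[[1L]]
  n1 <- summary$n1
  if (prior == "jeffreys") {
    list(prior = prior,
         beta_a = summary$n0 + 0.5, beta_b = n1 + 0.5,
         ig_shape = (n1 - 1) / 2,
         ig_scale = (n1 - 1) * summary$sigma2_hat / 2)
  } else {
    if (n1 < 3L)
      stop("the uniform prior needs at least 3 non-zero observations ",
           "(posterior shape would not be positive)", call. = FALSE)
    list(prior = prior,
         beta_a = summary$n0 + 1, beta_b = n1 + 1,
         ig_shape = (n1 - 2) / 2,
         ig_scale = (n1 - 2) * summary$sigma2_hat / 2)
  }
}

#' Posterior draws of the common CV
#'
#' Draws \code{delta = 1 - delta*} from the beta posterior and \code{sigma2}
#' from the inverse-gamma posterior of every group (inverse-gamma realized as
#' scale divided by a gamma variate), then maps each joint draw through the
#' weighted log-CV combination.
#'
#' By default (\code{weights = "per-draw"}) the combination weights are
#' re-evaluated at the drawn \code{(delta, sigma2)} of every replicate,
#' mirroring the fiducial treatment, with one numerical guard: the binomial
#' contribution of the substituted variance form is floored at zero.
#' Unfloored, that contribution turns negative whenever a drawn \code{delta}
#' falls below roughly \code{(n1-1)/(n-1)}, letting weight sums pass through
#' zero and blowing individual common-CV draws up without bound; flooring
#' restores the positivity a variance contribution must have (the methods
#' vignette discusses the choice and its validation).  The alternative
#' \code{weights = "data"} fixes the weights at the observed-data estimates,
#' as a sensitivity check.
#'
#' @param summaries list of non-degenerate [dln_summary()] objects.
#' @param prior \code{"jeffreys"} or \code{"uniform"}.
#' @param draws number of posterior draws (default 2000).
#' @param weights \code{"per-draw"} (default) or \code{"data"}; see Details.
#' @return Object of class \code{cv_draws} with matrices \code{delta},
#'   \code{sigma2}, \code{phi}, \code{weight} and the per-draw common-CV
#'   vector \code{eta}.
#' @export
posterior_common_cv <- function(summaries, prior = c("jeffreys", "uniform"),
                                draws = 2000L,
                                weights = c("per-draw", "data")) {
  prior <- match.arg(prior)
  weights <- match.arg(weights)
  summaries <- check_nondegenerate(summaries)
  k <- length(summaries)
  specs <- lapply(summaries, posterior_parameters, prior = prior)
  delta <- vapply(specs, function(p)
    1 - stats::rbeta(draws, p$beta_a, p$beta_b), numeric(draws))
  sigma2 <- vapply(specs, function(p)
    p$ig_scale / stats::rgamma(draws, shape = p$ig_shape), numeric(draws))
  delta <- matrix(delta, draws, k)
  sigma2 <- matrix(sigma2, draws, k)
  n <- vapply(summaries, `[[`, numeric(1), "n")
  n1 <- vapply(summaries, `[[`, numeric(1), "n1")
  if (weights == "data") {
    w0 <- 1 / vapply(summaries, var_phi_hat, numeric(1))
    phi <- phi_log_cv(sigma2, delta)
    w <- matrix(w0, draws, k, byrow = TRUE)
    parts <- list(phi = phi, var = 1 / w, weight = w,
                  eta = exp(rowSums(w * phi) / rowSums(w)))
  } else {
    parts <- common_cv_draw_matrix(delta, sigma2, n, n1,
                                   floor_binomial = TRUE)
  }
  structure(c(list(method = paste0("bayes_", prior), delta = delta,
                   sigma2 = sigma2), parts),
            class = "cv_draws")
}

#' Bayesian interval for the common CV
#'
#' Convenience wrapper combining [posterior_common_cv()] with either the
#' equal-tailed or the highest-posterior-density interval of the draws.
#'
#' @inheritParams posterior_common_cv
#' @param type \code{"equal-tailed"} or \code{"hpd"}.
#' @param level nominal credibility level.
#' @return A [cv_interval()] tagged \code{EB_*} or \code{HPD_*}.
#' @export
bayes_common_cv <- function(summaries, prior = c("jeffreys", "uniform"),
                            type = c("equal-tailed", "hpd"),
                            level = 0.95, draws = 2000L,
                            weights = c("per-draw", "data")) {
  prior <- match.arg(prior)
  type <- match.arg(type)
  post <- posterior_common_cv(summaries, prior, draws, weights)
  tag <- paste0(if (type == "hpd") "HPD_" else "EB_",
                if (prior == "jeffreys") "Jeffreys" else "Uniform")
  if (type == "hpd") hpd_interval(post, level, method = tag)
  else equal_tailed_interval(post, level, method = tag)
}
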