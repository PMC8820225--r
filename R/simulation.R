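# Monte Carlo engine: coverage probability and expected length of every
# interval method over a grid of delta-lognormal scenarios.

METHOD_KEYS <- c("FGCI", "EB_Jeffreys", "EB_Uniform",
                 "HPD_Jeffreys", "HPD_Uniform", "MOVER")

normalize_methods <- function(methods) {
  if (identical(methods, "all")) return(METHOD_KEYS)
  key <- gsub("-", "_", tolower(methods))
  map <- c(fgci = "FGCI",
           eb_jeffreys = "EB_Jeffreys", eb_uniform = "EB_Uniform",
           hpd_jeffreys = "HPD_Jeffreys", hpd_uniform = "HPD_Uniform",
           mover = "MOVER")
  out <- map[key]
  if (any(is.na(out)))
    stop("unknown method(s): ", paste(methods[is.na(out)], collapse = ", "),
         call. = FALSE)
  unname(out)
}

# Deterministic per-run substream seed derived from the master seed, so that
# individual runs are reproducible independently of execution order.
substream_seed <- function(seed, run) {
  as.integer((as.numeric(seed) * 1000003 + run) %% 2147483629)
}

#' Define a simulation scenario
#'
#' One cell of the coverage study: \code{k} groups of equal size \code{n},
#' all sharing the same true \code{delta} and \code{sigma2} (so the true
#' common CV is the single-group CV), evaluated with \code{runs} replicated
#' datasets and \code{draws} Monte Carlo draws per dataset for the fiducial
#' and Bayesian methods.
#'
#' @param k number of groups.
#' @param n per-group sample size.
#' @param delta true non-zero probability, shared by all groups.
#' @param sigma2 true log-scale variance, shared by all groups.
#' @param mu true log-scale mean (irrelevant to the CV; default 0).
#' @param level nominal confidence level.
#' @param runs number of simulated datasets.
#' @param draws Monte Carlo draws per dataset.
#' @param seed master seed; each run derives its own substream from it.
#' @return Object of class \code{cv_scenario}; carries \code{true_cv} and a
#'   \code{low_nonzero} flag when the expected non-zero count \code{n*delta}
#'   is below 8 (such cells are fragile and reported with a warning flag).
#' @export
scenario <- function(k, n, delta, sigma2, mu = 0, level = 0.95,
                     runs = 10000L, draws = 2000L, seed = NULL) {
  stopifnot(k >= 1, n >= 2, runs >= 1, draws >= 100)
  check_dln_params(delta, mu, sigma2)
  structure(list(k = as.integer(k), n = as.integer(n), delta = delta,
                 sigma2 = sigma2, mu = mu, level = level,
                 runs = as.integer(runs), draws = as.integer(draws),
                 seed = seed, true_cv = dln_cv(delta, sigma2),
                 low_nonzero = n * delta < 8),
            class = "cv_scenario")
}

#' Standard scenario grid of the coverage study
#'
#' The full cross of \code{k = 3, 5, 10}; \code{n = 25, 50, 100};
#' \code{delta = 0.2, 0.5, 0.8}; \code{sigma2 = 0.1, 0.5, 1.0, 2.0}
#' (108 cells) at the 95\% level.  Cells with expected non-zero count below
#' 8 (all \code{n = 25, delta = 0.2} combinations) carry the
#' \code{low_nonzero} flag.
#'
#' @param runs,draws,level passed to every [scenario()].
#' @param seed optional master seed shared by the cells.
#' @return List of \code{cv_scenario} objects.
#' @export
scenario_grid <- function(runs = 10000L, draws = 2000L, level = 0.95,
                          seed = NULL) {
  g <- expand.grid(sigma2 = c(0.1, 0.5, 1.0, 2.0), delta = c(0.2, 0.5, 0.8),
                   n = c(25L, 50L, 100L), k = c(3L, 5L, 10L),
                   KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    scenario(g$k[i], g$n[i], g$delta[i], g$sigma2[i], level = level,
             runs = runs, draws = draws, seed = seed))
}

#' Run one simulation scenario
#'
#' For every run: simulate \code{k} datasets, redrawing any dataset whose
#' groups do not all reach \code{min_n1} non-zero observations (redraws are
#' counted, not silently hidden); summarize; build each requested interval;
#' score whether it contains the true common CV and its length.
#'
#' @param sc a [scenario()].
#' @param methods \code{"all"} or a character subset of \code{fgci},
#'   \code{eb-jeffreys}, \code{eb-uniform}, \code{hpd-jeffreys},
#'   \code{hpd-uniform}, \code{mover}.
#' @param min_n1 minimum per-group non-zero count a simulated dataset must
#'   reach before it is analyzed (default 4).
#' @return Data frame with one row per method: coverage and its binomial
#'   standard error, expected length and its standard error, the count of
#'   redrawn datasets, and the largest common-CV draw observed (a diagnostic
#'   for the heavy right tail of the fiducial draws at large \code{sigma2}).
#' @export
run_scenario <- function(sc, methods = "all", min_n1 = 4L) {
  stopifnot(inherits(sc, "cv_scenario"))
  methods <- normalize_methods(methods)
  seed <- if (is.null(sc$seed)) sample.int(2147483629L, 1L) else sc$seed
  nm <- length(methods)
  cover <- matrix(NA, sc$runs, nm, dimnames = list(NULL, methods))
  len <- matrix(NA_real_, sc$runs, nm, dimnames = list(NULL, methods))
  rejected <- 0L
  max_draw <- stats::setNames(rep(-Inf, nm), methods)
  need_j <- any(methods %in% c("EB_Jeffreys", "HPD_Jeffreys"))
  need_u <- any(methods %in% c("EB_Uniform", "HPD_Uniform"))
  for (r in seq_len(sc$runs)) {
    set.seed(substream_seed(seed, r))
    repeat {
      data <- replicate(sc$k, rdln(sc$n, sc$delta, sc$mu, sc$sigma2),
                        simplify = FALSE)
      if (all(vapply(data, function(x) sum(x > 0), numeric(1)) >= min_n1))
        break
      rejected <- rejected + 1L
    }
    summaries <- lapply(data, summarize_dln)
    ints <- list()
    if ("FGCI" %in% methods) {
      piv <- pivotal_common_cv(summaries, sc$draws)
      ints$FGCI <- fgci_interval(piv, sc$level)
      max_draw["FGCI"] <- max(max_draw["FGCI"], max(piv$eta))
    }
    if (need_j) {
      post <- posterior_common_cv(summaries, "jeffreys", sc$draws)
      if ("EB_Jeffreys" %in% methods) {
        ints$EB_Jeffreys <- equal_tailed_interval(post, sc$level,
                                                  method = "EB_Jeffreys")
        max_draw["EB_Jeffreys"] <- max(max_draw["EB_Jeffreys"], max(post$eta))
      }
      if ("HPD_Jeffreys" %in% methods) {
        ints$HPD_Jeffreys <- hpd_interval(post, sc$level,
                                          method = "HPD_Jeffreys")
        max_draw["HPD_Jeffreys"] <- max(max_draw["HPD_Jeffreys"],
                                        max(post$eta))
      }
    }
    if (need_u) {
      post <- posterior_common_cv(summaries, "uniform", sc$draws)
      if ("EB_Uniform" %in% methods) {
        ints$EB_Uniform <- equal_tailed_interval(post, sc$level,
                                                 method = "EB_Uniform")
        max_draw["EB_Uniform"] <- max(max_draw["EB_Uniform"], max(post$eta))
      }
      if ("HPD_Uniform" %in% methods) {
        ints$HPD_Uniform <- hpd_interval(post, sc$level,
                                         method = "HPD_Uniform")
        max_draw["HPD_Uniform"] <- max(max_draw["HPD_Uniform"], max(post$eta))
      }
    }
    if ("MOVER" %in% methods)
      ints$MOVER <- mover_interval(summaries, sc$level)
    for (m in methods) {
      ci <- ints[[m]]
      cover[r, m] <- ci$lower <= sc$true_cv && sc$true_cv <= ci$upper
      len[r, m] <- ci$length
    }
  }
  cp <- colMeans(cover)
  el <- colMeans(len)
  data.frame(k = sc$k, n = sc$n, delta = sc$delta, sigma2 = sc$sigma2,
             level = sc$level, method = methods,
             coverage = cp,
             coverage_se = sqrt(cp * (1 - cp) / sc$runs),
             expected_length = el,
             length_se = apply(len, 2, stats::sd) / sqrt(sc$runs),
             rejected_runs = rejected,
             max_draw = ifelse(is.finite(max_draw), max_draw, NA_real_),
             runs = sc$runs, draws = sc$draws, seed = seed,
             row.names = NULL)
}

#' Apply the winner rule to scenario results
#'
#' Marks, per simulation cell, the methods whose coverage reaches the
#' nominal level, and among those the one with the shortest expected length.
#'
#' @param results data frame as returned by (possibly row-bound calls to)
#'   [run_scenario()].
#' @return The input with logical columns \code{covers_nominal} and
#'   \code{winner} added.
#' @export
summarize_results <- function(results) {
  if (nrow(results) == 0L) stop("no results", call. = FALSE)
  cell <- interaction(results$k, results$n, results$delta, results$sigma2,
                      drop = TRUE)
  results$covers_nominal <- results$coverage >= results$level
  results$winner <- FALSE
  for (cl in levels(cell)) {
    i <- which(cell == cl)
    elig <- i[results$covers_nominal[i]]
    if (length(elig) > 0L)
      results$winner[elig[which.min(results$expected_length[elig])]] <- TRUE
  }
  results
}
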