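# Data ingestion, fixture generation and report rendering.

#' Read grouped delta-lognormal data or summaries from CSV
#'
#' Two layouts are supported.  \code{"long"}: columns \code{group,value},
#' one row per observation; \code{value} must be non-negative and only an
#' exact 0 counts as a zero observation.  Rows with missing values are
#' dropped with a message.  \code{"summary"}: columns
#' \code{group,n,n1,mu_hat,sigma2_hat} (with \code{n1} optional when a
#' \code{delta_hat} column is present, and \code{mu_hat} optional), one row
#' per group, as printed in reports.
#'
#' @param path CSV file with a header.
#' @param format \code{"long"} or \code{"summary"}.
#' @return List of [dln_summary()] objects, in order of first appearance.
#' @export
read_groups <- function(path, format = c("long", "summary")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in ", path, call. = FALSE)
  if (format == "long") {
    if (!identical(sort(names(df)), c("group", "value")))
      stop("long format requires exactly the columns 'group,value'",
           call. = FALSE)
    drop <- !stats::complete.cases(df)
    if (any(drop)) {
      message("dropping ", sum(drop), " row(s) with missing values")
      df <- df[!drop, , drop = FALSE]
    }
    if (any(df$value < 0))
      stop("negative values at row(s): ",
           paste(utils::head(which(df$value < 0), 10L), collapse = ", "),
           call. = FALSE)
    groups <- unique(df$group)
    lapply(groups, function(g)
      summarize_dln(df$value[df$group == g], group = g))
  } else {
    needed <- c("group", "n", "sigma2_hat")
    if (!all(needed %in% names(df)))
      stop("summary format requires columns ",
           paste(needed, collapse = ","), call. = FALSE)
    if (!("n1" %in% names(df)) && !("delta_hat" %in% names(df)))
      stop("summary format requires an 'n1' or 'delta_hat' column",
           call. = FALSE)
    lapply(seq_len(nrow(df)), function(i)
      dln_summary(n = df$n[i],
                  n1 = if ("n1" %in% names(df)) df$n1[i] else NULL,
                  delta_hat = if ("delta_hat" %in% names(df)) df$delta_hat[i]
                              else NULL,
                  mu_hat = if ("mu_hat" %in% names(df)) df$mu_hat[i]
                           else NA_real_,
                  sigma2_hat = df$sigma2_hat[i],
                  group = df$group[i]))
  }
}

#' Write a synthetic long-format fixture
#'
#' Simulates one delta-lognormal sample per group and writes them as a
#' long-format CSV that round-trips through [read_groups()].
#'
#' @param groups data frame with columns \code{group}, \code{delta},
#'   \code{mu}, \code{sigma2}.
#' @param n per-group sample size (scalar or one per group).
#' @param path output CSV path.
#' @param seed optional seed for reproducible fixtures.
#' @return \code{path}, invisibly.
#' @export
generate_fixture <- function(groups, n, path, seed = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("group", "delta", "mu", "sigma2") %in% names(groups)))
  if (!is.null(seed)) set.seed(seed)
  n <- rep_len(n, nrow(groups))
  rows <- lapply(seq_len(nrow(groups)), function(i)
    data.frame(group = groups$group[i],
               value = rdln(n[i], groups$delta[i], groups$mu[i],
                            groups$sigma2[i])))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Full common-CV analysis of grouped data
#'
#' Reads (or accepts) per-group summaries, computes the common-CV point
#' estimate and every requested interval, and wraps them with provenance
#' (seed, draw count, package version) into a report object.
#'
#' @param input list of [dln_summary()] objects, or a CSV path understood by
#'   [read_groups()].
#' @param methods \code{"all"} or a subset of \code{fgci},
#'   \code{eb-jeffreys}, \code{eb-uniform}, \code{hpd-jeffreys},
#'   \code{hpd-uniform}, \code{mover}.
#' @param level confidence level.
#' @param draws Monte Carlo draws for the fiducial and Bayesian methods.
#' @param seed seed set before the Monte Carlo methods run.
#' @param format passed to [read_groups()] when \code{input} is a path.
#' @return Object of class \code{cv_report}.
#' @export
analyze_groups <- function(input, methods = "all", level = 0.95,
                           draws = 2000L, seed = NULL,
                           format = c("long", "summary")) {
  summaries <- if (is.character(input)) read_groups(input, format) else input
  summaries <- check_nondegenerate(summaries)
  methods <- normalize_methods(methods)
  if (!is.null(seed)) set.seed(seed)
  eta <- common_cv(summaries)
  ints <- lapply(methods, function(m) switch(m,
    FGCI = fgci_common_cv(summaries, level, draws),
    EB_Jeffreys = bayes_common_cv(summaries, "jeffreys", "equal-tailed",
                                  level, draws),
    EB_Uniform = bayes_common_cv(summaries, "uniform", "equal-tailed",
                                 level, draws),
    HPD_Jeffreys = bayes_common_cv(summaries, "jeffreys", "hpd", level, draws),
    HPD_Uniform = bayes_common_cv(summaries, "uniform", "hpd", level, draws),
    MOVER = mover_interval(summaries, level)))
  names(ints) <- methods
  anomalous <- vapply(ints, function(ci) eta < ci$lower || eta > ci$upper,
                      logical(1))
  structure(list(summaries = summaries, common_cv = eta, intervals = ints,
                 anomalous = anomalous,
                 provenance = list(seed = seed, draws = draws, level = level,
                                   package = "deltacv",
                                   version = as.character(
                                     utils::packageVersion("deltacv")))),
            class = "cv_report")
}

report_table <- function(report) {
  data.frame(method = vapply(report$intervals, `[[`, character(1), "method"),
             lower = vapply(report$intervals, `[[`, numeric(1), "lower"),
             upper = vapply(report$intervals, `[[`, numeric(1), "upper"),
             length = vapply(report$intervals, `[[`, numeric(1), "length"),
             row.names = NULL)
}

#' Render an analysis report
#'
#' @param report a \code{cv_report} from [analyze_groups()].
#' @param style \code{"text"} (aligned table, 4 decimals), \code{"csv"}, or
#'   \code{"json"} (lossless round-trip of the numbers).
#' @return Character vector of output lines (a single string for JSON).
#' @export
render_report <- function(report, style = c("text", "csv", "json")) {
  style <- match.arg(style)
  tab <- report_table(report)
  if (style == "text") {
    hdr <- sprintf("Common CV estimate: %.4f  (level %.2f, draws %d, seed %s)",
                   report$common_cv, report$provenance$level,
                   report$provenance$draws,
                   if (is.null(report$provenance$seed)) "none"
                   else report$provenance$seed)
    body <- c(sprintf("%-14s %10s %10s %10s", "method", "lower", "upper",
                      "length"),
              sprintf("%-14s %10.4f %10.4f %10.4f", tab$method, tab$lower,
                      tab$upper, tab$length))
    c(hdr, body)
  } else if (style == "csv") {
    tab$lower <- round(tab$lower, 4)
    tab$upper <- round(tab$upper, 4)
    tab$length <- round(tab$length, 4)
    c("method,lower,upper,length",
      sprintf("%s,%.4f,%.4f,%.4f", tab$method, tab$lower, tab$upper,
              tab$length))
  } else {
    jsonlite::toJSON(list(common_cv = report$common_cv,
                          intervals = tab,
                          provenance = report$provenance),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
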