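test_that("pivotal draws for the non-zero rate stay in (0,1] with the mixture mean", {
  set.seed(501)
  d <- pivotal_delta(45, 17, 1e5)
  expect_true(all(d > 0 & d <= 1))
  mix_mean <- 0.5 * 45 / 63 + 0.5 * 46 / 63
  # variance of each beta component is below 1/4; crude but safe bound
  expect_lt(abs(mean(d) - mix_mean), 4 * sqrt(0.25 / 1e5))
  # no zeros observed: second mixture component is a point mass at one
  set.seed(502)
  d0 <- pivotal_delta(12, 0, 4e4)
  expect_true(all(d0 > 0 & d0 <= 1))
  expect_lt(abs(mean(d0 == 1) - 0.5), 4 * sqrt(0.25 / 4e4))
  expect_error(pivotal_delta(0, 0, 10), "n1")
})

test_that("pivotal variance draws are positive inverse chi-square variates", {
  set.seed(503)
  s <- pivotal_sigma2(45, 1, 1e5)
  expect_true(all(s > 0))
  # mean of the scaled inverse chi-square: (n1-1)/(n1-3)
  se <- sqrt(stats::var(s) / 1e5)
  expect_lt(abs(mean(s) - 44 / 42), 4 * se)
  expect_error(pivotal_sigma2(1, 1, 10), "n1")
})

test_that("draws are reproducible under a fixed seed", {
  set.seed(504); a <- pivotal_delta(10, 5, 1000)
  set.seed(504); b <- pivotal_delta(10, 5, 1000)
  expect_identical(a, b)
  set.seed(504); pa <- pivotal_common_cv(rainfall_summaries(), 500)
  set.seed(504); pb <- pivotal_common_cv(rainfall_summaries(), 500)
  expect_identical(pa$eta, pb$eta)
})

test_that("common-CV pivot reduces to the point estimate when pinned at the data", {
  s <- dln_summary(50, n1 = 37, sigma2_hat = 1.4)
  pinned <- deltacv:::common_cv_draw_matrix(
    delta = matrix(s$delta_hat, 200, 1),
    sigma2 = matrix(1.4, 200, 1),
    n = 50, n1 = 37)
  expect_equal(unique(pinned$eta), exp(phi_log_cv(1.4, s$delta_hat)),
               tolerance = 1e-12)
})

test_that("pivotal common-CV draws have consistent shape and domains", {
  set.seed(505)
  piv <- pivotal_common_cv(rainfall_summaries(), 2000)
  expect_identical(dim(piv$delta), c(2000L, 3L))
  expect_identical(dim(piv$sigma2), c(2000L, 3L))
  expect_length(piv$eta, 2000L)
  expect_true(all(piv$delta > 0 & piv$delta <= 1))
  expect_true(all(piv$sigma2 > 0))
  expect_true(all(piv$eta > 0))
})

test_that("percentile interval follows the linear-interpolation convention", {
  ci <- fgci_interval(1:100, level = 0.95)
  expect_equal(ci$lower, 3.475, tolerance = 1e-12)
  expect_equal(ci$upper, 97.525, tolerance = 1e-12)
  # against a first-principles sort-based oracle
  set.seed(506)
  for (i in 1:5) {
    x <- stats::rlnorm(257, i / 3, 1)
    ci <- fgci_interval(x, level = 0.9)
    expect_equal(ci$lower, quantile_oracle(x, 0.05), tolerance = 1e-12)
    expect_equal(ci$upper, quantile_oracle(x, 0.95), tolerance = 1e-12)
  }
  expect_error(fgci_interval(1:50), "at least 100")
})

test_that("fiducial interval brackets the point estimate on the rainfall data", {
  set.seed(507)
  ci <- fgci_common_cv(rainfall_summaries(), draws = 4000)
  eta <- common_cv(rainfall_summaries())
  expect_lt(ci$lower, eta)
  expect_gt(ci$upper, eta)
  expect_lte(ci$lower, ci$upper)
})

test_that("fiducial interval concentrates around the truth for large samples", {
  set.seed(508)
  n <- 1e4
  x <- replicate(3, rdln(n, 0.6, 1, 0.9), simplify = FALSE)
  ci <- fgci_common_cv(lapply(x, summarize_dln), draws = 2000)
  truth <- dln_cv(0.6, 0.9)
  expect_lt(ci$length, 0.15)
  expect_lt(abs((ci$lower + ci$upper) / 2 - truth), 0.1)
})
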